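#' Classify residues as active or passive for restraint generation
#'
#' Active residues are solvent exposed (RSA at or above `cfg$rsa_threshold`)
#' with a CSP above `cfg$active_csp_threshold`. Passive residues are solvent
#' exposed residues that either lie within `cfg$passive_radius` (minimum
#' heavy-atom distance) of any active residue or whose CSP falls inside the
#' probe-type passive band. Active membership wins: the two sets are disjoint.
#' Residues lacking both a probe and proximity information are `"none"`;
#' probed residues without an RSA value are `"not_assessed"`.
#'
#' @param csps CSP tibble from [compute_csp()].
#' @param rsa RSA tibble from [relative_solvent_accessibility()] (same chain).
#' @param structure A `coord_ensemble` containing the chain; first frame used
#'   for the proximity rule.
#' @param chain Chain identifier of the molecule being classified.
#' @param cfg A [csp_config()].
#' @return A tibble with `resnum`, `resname`, `csp`, `rsa`, `class`
#'   (`active`/`passive`/`none`/`not_assessed`). Attributes `"active"` and
#'   `"passive"` carry the residue-number sets.
#' @export
classify_residues <- function(csps, rsa, structure, chain, cfg = csp_config()) {
  res <- rsa |>
    filter(.data$chain == !!chain) |>
    select("resnum", "resname", "rsa")
  probe_csp <- csps |>
    group_by(.data$residue) |>
    summarise(csp = max(.data$csp), probe_type = .data$probe_type[1],
              .groups = "drop")
  res <- left_join(res, probe_csp, by = c(resnum = "residue"))
  exposed <- !is.na(res$rsa) & res$rsa >= cfg$rsa_threshold
  has_csp <- !is.na(res$csp)
  active <- exposed & has_csp & res$csp > cfg$active_csp_threshold

  # proximity rule: minimum heavy-atom distance to any active residue
  active_res <- res$resnum[active]
  near_active <- rep(FALSE, nrow(res))
  if (length(active_res) > 0) {
    atoms <- structure$atoms
    xyz <- frame_coords(structure, 1L)
    heavy <- toupper(atoms$element) != "H" & atoms$chain == chain
    axyz <- xyz[heavy & atoms$resnum %in% active_res, , drop = FALSE]
    for (i in seq_len(nrow(res))) {
      if (active[i]) next
      sel <- heavy & atoms$resnum == res$resnum[i]
      if (!any(sel)) next
      dmin <- min(cross_distances(xyz[sel, , drop = FALSE], axyz))
      near_active[i] <- dmin <= cfg$passive_radius
    }
  }
  band <- t(vapply(seq_len(nrow(res)), function(i) {
    if (!has_csp[i]) return(c(NA_real_, NA_real_))
    b <- cfg$passive_band[[res$probe_type[i]]]
    if (is.null(b)) c(NA_real_, NA_real_) else b
  }, numeric(2)))
  in_band <- has_csp & !is.na(band[, 1]) &
    res$csp >= band[, 1] & res$csp <= band[, 2]
  passive <- exposed & !active & (near_active | in_band)

  cls <- rep("none", nrow(res))
  cls[has_csp & is.na(res$rsa)] <- "not_assessed"
  cls[passive] <- "passive"
  cls[active] <- "active"
  out <- tibble(resnum = res$resnum, resname = res$resname,
                csp = res$csp, rsa = res$rsa, class = cls)
  attr(out, "active") <- sort(res$resnum[active])
  attr(out, "passive") <- sort(res$resnum[passive])
  out
}
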