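#' Build ambiguous interaction restraints from classifications
#'
#' One ambiguous interaction restraint (AIR) per active residue of each
#' molecule, pooled against the union of the partner molecule's active and
#' passive residues. Active residues with an empty partner pool are skipped
#' with a warning. Output ordering is deterministic (chain, residue number).
#'
#' @param active_a,passive_a Integer residue numbers for molecule A.
#' @param active_b,passive_b Integer residue numbers for molecule B.
#' @param chain_a,chain_b Chain identifiers.
#' @param upper_bound Effective-distance upper bound in Angstrom (the
#'   1/r^6-pooled effective distance convention; 2.0 by default).
#' @return A tibble with columns `chain`, `resnum`, `partner_chain`,
#'   `partner_pool` (list column of residue numbers), `upper_bound`.
#' @export
build_airs <- function(active_a, passive_a, active_b, passive_b,
                       chain_a = "A", chain_b = "B", upper_bound = 2.0) {
  pool_b <- sort(unique(c(active_b, passive_b)))
  pool_a <- sort(unique(c(active_a, passive_a)))
  one_side <- function(active, chain, partner_chain, pool) {
    if (length(active) == 0) return(NULL)
    if (length(pool) == 0) {
      warn(paste0("empty partner pool for active residues of chain ", chain,
                  "; restraints skipped"))
      return(NULL)
    }
    tibble(chain = chain, resnum = sort(unique(active)),
           partner_chain = partner_chain,
           partner_pool = list(pool), upper_bound = upper_bound)
  }
  if (length(active_a) == 0 && length(active_b) == 0) {
    warn("no active residues on either molecule; empty AIR set")
  }
  out <- bind_rows(one_side(active_a, chain_a, chain_b, pool_b),
                   one_side(active_b, chain_b, chain_a, pool_a))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(chain = character(), resnum = integer(),
                  partner_chain = character(), partner_pool = list(),
                  upper_bound = numeric())
  }
  out
}

#' Distance restraints from a PRE profile
#'
#' Every probe whose paramagnetic/diamagnetic intensity ratio falls below
#' `threshold` -- including probes broadened beyond detection -- yields one
#' restraint between the spin-label site and the probe protons with bounds
#' `[lower, upper]` Angstrom.
#'
#' @param profile Ratio tibble as from [intensity_ratio_profile()] or
#'   [gen_pre_profiles()] (columns `probe`, `residue`, `atom_group`, `ratio`,
#'   `vanished`).
#' @param label_site List with `chain`, `resnum`, `atom` identifying the
#'   paramagnetic-centre pseudo-atom.
#' @param probe_chain Chain carrying the probes.
#' @param threshold Ratio below which a restraint is emitted.
#' @param lower,upper Distance bounds (Angstrom).
#' @return Tibble of restraints (`chain_a`, `resnum_a`, `atom_a`, `chain_b`,
#'   `resnum_b`, `atom_b`, `lower`, `upper`).
#' @export
pre_restraints <- function(profile, label_site, probe_chain = "B",
                           threshold = 0.2, lower = 1.8, upper = 16.0) {
  stopifnot_named("bounds must satisfy 0 < lower <= upper" =
                    lower > 0 && lower <= upper)
  hit <- profile$ratio < threshold | profile$vanished
  sel <- profile[hit, , drop = FALSE]
  tibble(chain_a = label_site$chain, resnum_a = label_site$resnum,
         atom_a = label_site$atom,
         chain_b = probe_chain, resnum_b = sel$residue,
         atom_b = paste0("H", sel$atom_group),  # methyl protons, OR-selected
         lower = lower, upper = upper)
}

#' Serialize a restraint set to a CNS/docking-style .tbl file
#'
#' AIRs are written as nested OR selections with effective distance d = 2.0,
#' dminus = 2.0, dplus = 0; unambiguous restraints as d = upper,
#' dminus = upper - lower, dplus = 0. Output is byte-stable for fixed input.
#' [read_tbl()] parses the same dialect back into the two tibbles.
#'
#' @param airs AIR tibble from [build_airs()] (may be `NULL`).
#' @param unambiguous Distance restraint tibble from [pre_restraints()]
#'   (may be `NULL`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tbl <- function(airs, unambiguous, path) {
  lines <- c("! restraint table (CNS assign dialect)")
  if (!is.null(airs) && nrow(airs) > 0) {
    for (i in seq_len(nrow(airs))) {
      pool <- airs$partner_pool[[i]]
      sel <- paste(sprintf("(segid %s and resid %d)",
                           airs$partner_chain[i], pool),
                   collapse = " or ")
      lines <- c(lines, sprintf(
        "assign (segid %s and resid %d) (%s) %.1f %.1f 0.0",
        airs$chain[i], airs$resnum[i], sel,
        airs$upper_bound[i], airs$upper_bound[i]))
    }
  }
  if (!is.null(unambiguous) && nrow(unambiguous) > 0) {
    for (i in seq_len(nrow(unambiguous))) {
      u <- unambiguous[i, ]
      lines <- c(lines, sprintf(
        "assign (segid %s and resid %d and name %s) (segid %s and resid %d and name %s) %.2f %.2f 0.0",
        u$chain_a, u$resnum_a, u$atom_a, u$chain_b, u$resnum_b, u$atom_b,
        u$upper, u$upper - u$lower))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tbl
#' @export
read_tbl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  airs <- list(); unam <- list()
  sel_re <- "segid (\\S+) and resid (\\d+)(?: and name (\\S+?))?\\)"
  for (ln in lines) {
    nums <- regmatches(ln, regexec("\\) ([0-9.]+) ([0-9.]+) ([0-9.]+)\\s*$", ln))[[1]]
    d <- as.numeric(nums[2]); dminus <- as.numeric(nums[3])
    # columns of `sels` are the matches; row 2 = segid, 3 = resid, 4 = name
    sels <- regmatches(ln, gregexec(sel_re, ln, perl = TRUE))[[1]]
    has_names <- any(nzchar(sels[4, ]))
    if (has_names) {
      unam[[length(unam) + 1]] <- tibble(
        chain_a = sels[2, 1], resnum_a = as.integer(sels[3, 1]),
        atom_a = sels[4, 1],
        chain_b = sels[2, 2], resnum_b = as.integer(sels[3, 2]),
        atom_b = sels[4, 2],
        lower = d - dminus, upper = d)
    } else {
      airs[[length(airs) + 1]] <- tibble(
        chain = sels[2, 1], resnum = as.integer(sels[3, 1]),
        partner_chain = sels[2, 2],
        partner_pool = list(as.integer(sels[3, -1])),
        upper_bound = d)
    }
  }
  list(airs = bind_rows(airs), unambiguous = bind_rows(unam))
}
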