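#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join group_by
#'   summarise ungroup bind_rows rename distinct pull n across
#' @importFrom stats lm coef cor sd setNames approx rnorm runif optimize weighted.mean
#' @importFrom graphics hist
#' @importFrom utils head tail read.csv write.csv modifyList
#' @useDynLib allogap
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# single shared assertion helper: all conditions must be TRUE
stopifnot_named <- function(...) {
  conds <- list(...)
  nms <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) abort(nms[i] %||% "internal assertion failed")
  }
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# probe id convention used across peak tables, PRE profiles and restraints
probe_id <- function(residue_number, residue_name, atom_group) {
  paste(residue_number, residue_name, atom_group, sep = ".")
}

vapply_dbl <- function(x, f, ...) vapply(x, f, numeric(1), ...)
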