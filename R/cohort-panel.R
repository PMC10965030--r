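#' Analysis-ready longitudinal cohort panel
#'
#' A `cohort_panel` is a long-format data frame with one row per individual
#' and scheduled wave, carrying the Frailty Index (FI), the covariates used
#' by the trajectory models, and the observation/vital-status indicators that
#' drive the weighting machinery.
#'
#' Required columns:
#' \describe{
#'   \item{id}{individual identifier}
#'   \item{wave}{integer wave index, 1-based}
#'   \item{age}{age at the wave, in years}
#'   \item{sex}{1 = female, 0 = male}
#'   \item{educ_years}{years of full-time education}
#'   \item{base_age}{age at study entry, in years}
#'   \item{born_1946plus}{1 = born in 1946 or later, 0 = earlier}
#'   \item{fi}{Frailty Index in \[0, 1\], `NA` when the wave was not observed}
#'   \item{observed}{1 if the individual was interviewed at the wave}
#'   \item{alive}{1 if the individual was alive at the wave}
#' }
#'
#' Validated invariants: an observed row is alive; a non-missing FI implies
#' an observed row; each individual's first wave is observed; and `alive` is
#' monotone non-increasing within individual (death is absorbing).
#'
#' @param x data frame with the columns above (extra columns are kept).
#' @return `x` with class `cohort_panel`, sorted by id and wave.
#' @examples
#' pan <- simulate_cohort(sim_config(n_individuals = 50, seed = 1))
#' head(pan)
#' @export
as_cohort_panel <- function(x) {
  x <- as.data.frame(x)
  req <- c("id", "wave", "age", "sex", "educ_years", "base_age",
           "born_1946plus", "fi", "observed", "alive")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("cohort_panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- x[order(x$id, x$wave), , drop = FALSE]
  rownames(x) <- NULL
  if (any(x$observed == 1 & x$alive == 0)) {
    stop("cohort_panel invariant violated: observed rows must be alive",
         call. = FALSE)
  }
  if (any(!is.na(x$fi) & x$observed == 0)) {
    stop("cohort_panel invariant violated: FI present on unobserved rows",
         call. = FALSE)
  }
  first <- !duplicated(x$id)
  if (any(x$observed[first] != 1)) {
    stop("cohort_panel invariant violated: first wave of each individual ",
         "must be observed (study entry)", call. = FALSE)
  }
  dal <- stats::ave(x$alive, x$id, FUN = function(a) c(0, diff(a)))
  if (any(dal > 0)) {
    stop("cohort_panel invariant violated: alive flag must be monotone ",
         "non-increasing within individual", call. = FALSE)
  }
  class(x) <- c("cohort_panel", "data.frame")
  x
}

#' @export
print.cohort_panel <- function(x, ...) {
  ni <- length(unique(x$id))
  cat(sprintf("<cohort_panel> %d individuals x %d waves (%d rows)\n",
              ni, max(x$wave), nrow(x)))
  cat(sprintf("  observed person-waves: %d; deaths: %d (%.1f%%)\n",
              sum(x$observed),
              sum(tapply(x$alive, x$id, min) == 0),
              100 * mean(tapply(x$alive, x$id, min) == 0)))
  cf <- attr(x, "clamp_frac")
  if (!is.null(cf)) cat(sprintf("  FI values clamped to [0,1]: %.2f%%\n", 100 * cf))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Read / write a cohort panel as CSV
#'
#' Plain-text round trip for [as_cohort_panel()] panels.
#'
#' @param path file path.
#' @param panel a `cohort_panel`.
#' @return `read_cohort_panel` returns a validated `cohort_panel`;
#'   `write_cohort_panel` returns `path` invisibly.
#' @export
read_cohort_panel <- function(path) {
  as_cohort_panel(utils::read.csv(path))
}

#' @rdname read_cohort_panel
#' @export
write_cohort_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
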