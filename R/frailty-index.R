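#' Declarative coding rule for one deficit item
#'
#' An `item_spec` maps the raw values of a survey/assessment item to a
#' deficit score in \[0, 1\] (or missing). Two rule types cover the usual
#' deficit codings:
#' \describe{
#'   \item{threshold}{numeric items: deficit (1) when the value is `>=`
#'     (`direction = "ge"`) or `<=` (`direction = "le"`) the cutoff, 0
#'     otherwise.}
#'   \item{map}{categorical (or discrete numeric) items: an explicit
#'     value-to-score map; fractional scores such as 0.5 for intermediate
#'     categories are allowed.}
#' }
#' Raw values not covered by the rule become missing and are counted as
#' unmapped (reported with a warning by [apply_item_spec()]); `NA` input is
#' missing without warning.
#'
#' @param item_id column name of the item in the raw panel.
#' @param type `"threshold"` or `"map"`.
#' @param description free-text label.
#' @param cutoff,direction threshold rule parameters.
#' @param map named numeric vector (names = raw values as strings, values =
#'   deficit scores in \[0, 1\]).
#' @return an object of class `item_spec`.
#' @examples
#' item_spec("n_chronic", "threshold", cutoff = 3, direction = "ge")
#' item_spec("self_rated_health", "map",
#'           map = c(poor = 1, fair = 0.5, good = 0))
#' @export
item_spec <- function(item_id, type = c("threshold", "map"),
                      description = "", cutoff = NULL,
                      direction = c("ge", "le"), map = NULL) {
  type <- match.arg(type)
  if (type == "threshold") {
    direction <- match.arg(direction)
    if (is.null(cutoff) || !is.numeric(cutoff)) {
      stop_config("cutoff", "threshold items need a numeric cutoff")
    }
  } else {
    if (is.null(map) || is.null(names(map)) ||
        any(!is.na(map) & (map < 0 | map > 1))) {
      stop_config("map", "map items need a named vector of scores in [0, 1]")
    }
  }
  structure(list(item_id = item_id, type = type, description = description,
                 cutoff = cutoff, direction = direction, map = map),
            class = "item_spec")
}

#' Read a list of item specs from a YAML file
#'
#' The file holds one entry per item with fields `item_id`, `type` and the
#' rule parameters of [item_spec()]. A synthetic 40-item battery in this
#' format ships with the package:
#' `system.file("extdata", "item_spec_synthetic_40.yaml", package = "frailtyq")`.
#'
#' @param path YAML file path.
#' @return list of `item_spec` objects.
#' @export
read_item_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) {
    item_spec(item_id = e$item_id, type = e$type,
              description = e$description %||% "",
              cutoff = e$cutoff, direction = e$direction %||% "ge",
              map = if (!is.null(e$map)) unlist(e$map))
  })
}

#' Score a raw item panel into a deficit panel
#'
#' Applies each item's coding rule column-wise. The result keeps the `id`
#' and `wave` columns and replaces each raw item column by its deficit score
#' (0, 1, a fraction, or `NA`).
#'
#' @param raw_panel data frame with `id`, `wave` and one column per
#'   `item_id`.
#' @param specs list of [item_spec()] objects.
#' @return a `deficit_panel` data frame; attribute `n_unmapped` counts raw
#'   values that no rule covered (also surfaced as a warning).
#' @examples
#' raw <- data.frame(id = 1, wave = 1:3, grip = c(1, 3, NA))
#' sp <- list(item_spec("grip", "threshold", cutoff = 3, direction = "ge"))
#' apply_item_spec(raw, sp)
#' @export
apply_item_spec <- function(raw_panel, specs) {
  ids <- vapply(specs, function(s) s$item_id, "")
  absent <- setdiff(ids, names(raw_panel))
  if (length(absent)) {
    stop("item spec refers to absent columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n_unmapped <- 0L
  out <- raw_panel[c("id", "wave")]
  for (s in specs) {
    v <- raw_panel[[s$item_id]]
    if (s$type == "threshold") {
      vn <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(vn)
      score <- if (s$direction == "ge") as.numeric(vn >= s$cutoff)
               else as.numeric(vn <= s$cutoff)
      score[bad] <- NA_real_
      n_unmapped <- n_unmapped + sum(bad)
    } else {
      key <- as.character(v)
      score <- unname(s$map[key])
      bad <- !is.na(v) & !(key %in% names(s$map))
      n_unmapped <- n_unmapped + sum(bad)
    }
    out[[s$item_id]] <- score
  }
  if (n_unmapped > 0) {
    warning(sprintf("%d raw values not covered by any coding rule; set to missing",
                    n_unmapped), call. = FALSE)
  }
  class(out) <- c("deficit_panel", "data.frame")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Compute the deficit-accumulation Frailty Index
#'
#' For each row, FI = (sum of non-missing deficit scores) / (number of
#' non-missing items), computed only when the number of valid (non-missing)
#' items is at least `min_valid`; otherwise the FI is missing. The defaults
#' encode the common 40-item battery with a >= 35-valid-items rule. The
#' denominator is the number of items actually considered (the standard
#' deficit-accumulation convention), so a missing item changes the validity
#' count but never the FI among the remaining items.
#'
#' @param deficits a `deficit_panel` from [apply_item_spec()], or any data
#'   frame with `id`, `wave` and K deficit-score columns.
#' @param min_valid minimum number of non-missing items for a valid FI.
#' @param n_items expected battery size K (checked against the panel).
#' @return data frame `id`, `wave`, `n_valid`, `fi`.
#' @examples
#' d <- data.frame(id = 1, wave = 1, matrix(c(rep(1, 10), rep(0, 30)), 1))
#' compute_fi(d)$fi  # 10 deficits over 40 valid items = 0.25
#' @export
compute_fi <- function(deficits, min_valid = 35, n_items = 40) {
  if (min_valid > n_items) {
    stop_config("min_valid", "cannot exceed n_items")
  }
  cols <- setdiff(names(deficits), c("id", "wave"))
  if (length(cols) != n_items) {
    stop(sprintf("deficit panel has %d item columns but n_items = %d",
                 length(cols), n_items), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(deficits)[cols])
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("deficit scores must lie in [0, 1]", call. = FALSE)
  }
  n_valid <- rowSums(!is.na(m))
  fi <- rowSums(m, na.rm = TRUE) / n_valid
  fi[n_valid < min_valid] <- NA_real_
  fi[n_valid == 0] <- NA_real_
  data.frame(id = deficits$id, wave = deficits$wave,
             n_valid = n_valid, fi = fi)
}

#' Simulate a raw deficit-item panel consistent with a cohort panel
#'
#' Generates K binary items per observed person-wave with item probability
#' equal to the row's FI (plus item-specific difficulty jitter), and sprinkles
#' item-level missingness. Used to exercise the FI-construction path end to
#' end on synthetic data; the aggregate of the items recovers the FI up to
#' binomial noise.
#'
#' @param panel a [as_cohort_panel()] with non-missing `fi` rows.
#' @param n_items battery size.
#' @param miss_prob per-item missingness probability.
#' @param seed RNG seed.
#' @return data frame `id`, `wave`, `item_01`..`item_K` with 0/1/NA values.
#' @export
simulate_deficit_items <- function(panel, n_items = 40, miss_prob = 0.02,
                                   seed = 1L) {
  obs <- panel[!is.na(panel$fi), c("id", "wave", "fi")]
  with_seed(seed, {
    m <- matrix(stats::rbinom(nrow(obs) * n_items, 1,
                              rep(pmin(pmax(obs$fi, 0), 1), n_items)),
                nrow = nrow(obs))
    m[stats::runif(length(m)) < miss_prob] <- NA_integer_
    colnames(m) <- sprintf("item_%02d", seq_len(n_items))
    cbind(obs[c("id", "wave")], as.data.frame(m))
  })
}
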