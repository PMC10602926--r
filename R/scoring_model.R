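#' Scoring model for tri-loop response elements
#'
#' Builds the model object that controls hairpin enumeration, site scoring
#' and categorization. The structural definition of a response element is
#' fixed (a tri-loop hairpin whose third loop nucleotide is a purine and
#' whose loop-closing stem pair is U-A or C-G, read 5' strand first); the
#' stem-length bounds, wobble policy, per-position weights, category
#' thresholds and UTR-location weights are all configurable here.
#'
#' @details
#' The per-position weight table of the original binding-strength model is
#' not public; the default table shipped here is a documented stand-in with
#' the same qualitative structure: contributions from the three loop
#' positions, the identity of the loop-closing pair, and each additional
#' stem pair (G-C > A-U > G-U). It is calibrated so that a minimally valid
#' site scores at least the lowest category threshold and an all-optimal
#' site with a full-length stem scores into the top category. Supply
#' `position_weights` (or a YAML config via [scoring_model_from_config()])
#' to replace it.
#'
#' Weight table keys: `loop1.<base>`, `loop2.<base>`, `loop3.<base>` for
#' the three loop nucleotides; `closing.<b5><b3>` for the loop-closing pair
#' (5' base first); `stem.<b5><b3>` for every non-closing stem pair
#' (position-independent). Absent keys contribute 0.
#'
#' @param min_stem,max_stem integer stem-length bounds (base pairs),
#'   counting the loop-closing pair. Defaults 3 and 8.
#' @param allow_wobble allow G-U pairs in non-closing stem positions.
#' @param position_weights named numeric vector, see Details.
#' @param thresholds strictly ascending numeric vector of four category
#'   lower bounds (inclusive). Default `c(0.225, 0.45, 0.9, 1.8)`, twofold
#'   steps.
#' @param utr_weights named numeric vector with entries `five_prime` and
#'   `three_prime`, multiplying site scores in the per-mRNA aggregate.
#' @return An object of class `lre_scoring_model`.
#' @examples
#' m <- lre_scoring_model()
#' categorize(c(0.2, 0.225, 0.5, 1.0, 2.5), m)
#' @export
lre_scoring_model <- function(min_stem = 3L, max_stem = 8L,
                              allow_wobble = TRUE,
                              position_weights = default_position_weights(),
                              thresholds = c(0.225, 0.45, 0.9, 1.8),
                              utr_weights = c(five_prime = 1, three_prime = 1)) {
  min_stem <- as.integer(min_stem); max_stem <- as.integer(max_stem)
  if (min_stem < 2L) input_error("min_stem must be >= 2 (got %d)", min_stem)
  if (max_stem < min_stem)
    input_error("max_stem (%d) must be >= min_stem (%d)", max_stem, min_stem)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    input_error("thresholds must be four strictly ascending values")
  if (!all(c("five_prime", "three_prime") %in% names(utr_weights)) ||
      any(utr_weights[c("five_prime", "three_prime")] <= 0))
    input_error("utr_weights must be positive and name five_prime and three_prime")
  if (is.null(names(position_weights)) || !is.numeric(position_weights))
    input_error("position_weights must be a named numeric vector")
  structure(
    list(min_stem = min_stem, max_stem = max_stem,
         allow_wobble = isTRUE(allow_wobble),
         position_weights = position_weights,
         thresholds = thresholds,
         category_names = c("minimal", "weak", "medium", "strong"),
         utr_weights = utr_weights[c("five_prime", "three_prime")]),
    class = "lre_scoring_model")
}

#' Default position-weight table (stand-in)
#'
#' See [lre_scoring_model()] for the key conventions and the calibration
#' targets this table satisfies.
#' @return Named numeric vector of weights.
#' @export
default_position_weights <- function() {
  c(loop1.U = 0.10,
    loop2.C = 0.10,
    loop3.A = 0.075, loop3.G = 0.125,
    closing.UA = 0.10, closing.CG = 0.15,
    stem.GC = 0.20, stem.CG = 0.20,
    stem.AU = 0.10, stem.UA = 0.10,
    stem.GU = 0.05, stem.UG = 0.05)
}

#' Assign a category to a score
#'
#' Categories have inclusive lower bounds at the model thresholds: with the
#' defaults, minimal = \[0.225, 0.45), weak = \[0.45, 0.9),
#' medium = \[0.9, 1.8), strong = \[1.8, Inf). Scores below the lowest
#' threshold get `NA` (not a site).
#'
#' @param score numeric vector of non-negative scores.
#' @param model an [lre_scoring_model()].
#' @return Factor with levels minimal < weak < medium < strong; `NA` below
#'   the minimal threshold.
#' @export
categorize <- function(score, model = lre_scoring_model()) {
  if (any(score < 0, na.rm = TRUE)) input_error("scores must be non-negative")
  idx <- findInterval(score, model$thresholds)
  factor(ifelse(idx == 0L, NA_character_, model$category_names[pmax(idx, 1L)]),
         levels = model$category_names, ordered = TRUE)
}

#' @export
print.lre_scoring_model <- function(x, ...) {
  cat("Tri-loop response-element scoring model\n")
  cat(sprintf("  stem length: %d-%d bp; G-U wobble: %s (never at the closing pair)\n",
              x$min_stem, x$max_stem,
              if (x$allow_wobble) "allowed" else "disallowed"))
  cat(sprintf("  category thresholds (inclusive lower bounds): %s\n",
              paste(sprintf("%s>=%g", x$category_names, x$thresholds),
                    collapse = ", ")))
  cat(sprintf("  UTR weights: 5'=%g 3'=%g\n",
              x$utr_weights[["five_prime"]], x$utr_weights[["three_prime"]]))
  cat(sprintf("  %d position-weight entries\n", length(x$position_weights)))
  invisible(x)
}

#' Build a scoring model from a YAML config file
#'
#' The file may set any of the fields of [lre_scoring_model()];
#' `position_weights` is given as a mapping from key to weight.
#' Unset fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @return An `lre_scoring_model`.
#' @export
scoring_model_from_config <- function(path) {
  if (!file.exists(path)) input_error("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (f in c("min_stem", "max_stem", "allow_wobble", "thresholds"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$position_weights))
    args$position_weights <- unlist(cfg$position_weights)
  if (!is.null(cfg$utr_weights))
    args$utr_weights <- unlist(cfg$utr_weights)
  do.call(lre_scoring_model, args)
}
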