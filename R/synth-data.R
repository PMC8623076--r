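#' Generate synthetic composite-sample contamination data
#'
#' Draws per-sample wet-weight element concentrations from lognormal
#' distributions moment-matched to the target mean and standard deviation of
#' each species x element group (`sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`), emulating composite-sample ICP
#' measurements. Lognormal is the conventional family for contaminant
#' residues: strictly positive and right-skewed. A group with `sd = 0`
#' yields constant draws at the mean. Draws falling below the
#' tissue-equivalent LOD for their element are flagged censored and their
#' numeric value withheld (`NA`), as a real instrument report would.
#'
#' @param specs A tibble of target moments with columns `species`, `element`,
#'   `mean`, `sd`, `n_samples` (and optionally `unit`); see
#'   [reference_composition()]. Means must be positive, sds non-negative.
#' @param lod_table Optional tibble with columns `element`, `lod` giving the
#'   tissue-equivalent LOD in the same units as the spec mean; elements
#'   without an entry are never censored (LOD 0).
#' @param seed Integer seed; regeneration with the same seed is
#'   byte-identical.
#' @param n_override Optional single count replacing every spec's
#'   `n_samples` (used for moment-recovery checks at large n).
#' @return A tibble with columns `species`, `sample_id`, `element`,
#'   `value_ww` (`NA` when censored), `unit`, `censored`, `lod`.
#' @export
#' @examples
#' specs <- reference_composition("Mizuhopecten yessoensis", "Cd")
#' generate_contamination(specs, seed = 1)
generate_contamination <- function(specs, lod_table = NULL, seed,
                                   n_override = NULL) {
  stopifnot(is.data.frame(specs), nrow(specs) > 0)
  req <- c("species", "element", "mean", "sd", "n_samples")
  if (!all(req %in% names(specs))) {
    stop("specs must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(specs$mean <= 0) || any(specs$sd < 0) || any(specs$n_samples < 1)) {
    stop("invalid spec: need mean > 0, sd >= 0, n_samples >= 1",
         call. = FALSE)
  }
  if (is.null(specs$unit)) specs$unit <- element_unit(specs$element)
  set.seed(seed)
  rows <- purrr::pmap_dfr(
    specs[, c(req, "unit")],
    function(species, element, mean, sd, n_samples, unit) {
      n <- if (is.null(n_override)) n_samples else n_override
      if (sd == 0) {
        x <- rep(mean, n)
      } else {
        sigma2 <- log(1 + (sd / mean)^2)
        mu <- log(mean) - sigma2 / 2
        x <- stats::rlnorm(n, mu, sqrt(sigma2))
      }
      lod <- 0
      if (!is.null(lod_table)) {
        hit <- match(element, lod_table$element)
        if (!is.na(hit)) lod <- lod_table$lod[hit]
      }
      censored <- x < lod
      tibble::tibble(
        species = species,
        sample_id = sprintf("%s-%02d", abbreviate(species, 6), seq_len(n)),
        element = element,
        value_ww = ifelse(censored, NA_real_, x),
        unit = unit,
        censored = censored,
        lod = lod
      )
    }
  )
  rows
}

#' Specification of a synthetic food-frequency questionnaire
#'
#' @param n_respondents Number of respondents (the study surveyed 142).
#' @param frequency_probs Tibble with columns `label`, `prob` over the nine
#'   frequency categories; probabilities must sum to 1 within 1e-9.
#' @param pieces_probs Tibble with columns `label`, `prob` over the six
#'   pieces-per-meal ranges; probabilities must sum to 1 within 1e-9.
#' @return An object of class `"ffq_spec"`.
#' @export
ffq_spec <- function(n_respondents = 142,
                     frequency_probs = default_frequency_categories(),
                     pieces_probs = default_pieces_categories()) {
  stopifnot(n_respondents >= 1)
  for (tab in list(frequency_probs, pieces_probs)) {
    if (any(tab$prob < 0) || abs(sum(tab$prob) - 1) > 1e-9) {
      stop("category probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  structure(
    list(n_respondents = as.integer(n_respondents),
         frequency_probs = frequency_probs, pieces_probs = pieces_probs),
    class = "ffq_spec"
  )
}

#' Generate a synthetic food-frequency questionnaire table
#'
#' Assigns each respondent one consumption-frequency category and one
#' pieces-per-meal category by independent draws from the spec's category
#' probabilities, emulating the consumption survey the exposure assessment
#' is built on.
#'
#' @param spec An [ffq_spec()] object.
#' @param species Species label attached to every row (a survey covers one
#'   species' consumption questions at a time).
#' @param seed Integer seed.
#' @return A tibble with columns `respondent_id`, `species`, `freq_category`,
#'   `pieces_category`.
#' @export
#' @examples
#' generate_ffq(ffq_spec(n_respondents = 10), "Mizuhopecten yessoensis", 1)
generate_ffq <- function(spec, species, seed) {
  stopifnot(inherits(spec, "ffq_spec"))
  set.seed(seed)
  n <- spec$n_respondents
  freq <- sample(spec$frequency_probs$label, n, replace = TRUE,
                 prob = spec$frequency_probs$prob)
  pieces <- sample(spec$pieces_probs$label, n, replace = TRUE,
                   prob = spec$pieces_probs$prob)
  tibble::tibble(
    respondent_id = seq_len(n),
    species = species,
    freq_category = freq,
    pieces_category = pieces
  )
}

#' Generate a synthetic elemental fingerprint matrix
#'
#' Builds the samples x elements concentration matrix used by the
#' chemometric module: per species, `n_samples` draws per element from the
#' moment-matched lognormal generator (no censoring), arranged with one row
#' per composite sample and one column per element.
#'
#' @param specs Moment table as in [generate_contamination()]; defaults to
#'   the full published composition (48 samples x 16 elements).
#' @param seed Integer seed.
#' @return A list with `X` (numeric matrix, rownames = sample ids), `labels`
#'   (species per row), `element_names`.
#' @export
generate_fingerprints <- function(specs = reference_composition(), seed) {
  long <- generate_contamination(specs, lod_table = NULL, seed = seed)
  wide <- tidyr::pivot_wider(
    long[, c("species", "sample_id", "element", "value_ww")],
    names_from = "element", values_from = "value_ww"
  )
  elements <- setdiff(names(wide), c("species", "sample_id"))
  X <- as.matrix(wide[, elements])
  rownames(X) <- wide$sample_id
  list(X = X, labels = wide$species, element_names = elements)
}
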