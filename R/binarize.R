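#' Binarization schemes
#'
#' Constructors for the binary-transformation specifications applied to
#' valued informant networks:
#'
#' * `rating_scheme(cutoff)` — teacher ratings: tie present when the
#'   rating is at or above `cutoff` (1 "rarely play", 2 "sometimes play",
#'   3 "often play" are the conventional choices).
#' * `ratio_scheme(type, p)` — researcher counts, row-normalized: tie from
#'   i to j when i's share of interactions directed at j is at or above a
#'   baseline. `"chance"` uses `1/(n_eff - 1)` (the share expected if a
#'   child spread interactions uniformly over classmates),
#'   `"twice_chance"` doubles it, `"fixed"` uses a constant `p`
#'   (conventionally 5%).
#' * `frequency_scheme(rule, q, k)` — researcher counts, raw frequencies:
#'   `"half_median"` ties pairs whose frequency is strictly above half the
#'   median pair frequency (zero-count pairs included in the median);
#'   `"percentile"` ties pairs at or above the nearest-rank `q`-th
#'   percentile of the pair-frequency distribution; `"fixed"` uses the
#'   constant cutoff `k`.
#'
#' @param cutoff integer rating cutoff in `0:4`.
#' @param type ratio baseline: `"chance"`, `"twice_chance"`, or `"fixed"`.
#' @param p fixed ratio baseline in `(0, 1)` (only for `type = "fixed"`).
#' @param rule frequency rule: `"half_median"`, `"percentile"`, or
#'   `"fixed"`.
#' @param q percentile in `(0, 100)` (only for `rule = "percentile"`).
#' @param k fixed frequency cutoff (only for `rule = "fixed"`).
#'
#' @return An object of class `"binarization_spec"`.
#' @examples
#' rating_scheme(2)
#' ratio_scheme("twice_chance")
#' frequency_scheme("percentile", q = 90)
#' @name binarization_spec
NULL

#' @rdname binarization_spec
#' @export
rating_scheme <- function(cutoff) {
  if (length(cutoff) != 1 || !is_wholenumber(cutoff) || cutoff < 0 ||
      cutoff > 4) {
    stop("rating cutoff must be a single integer on the 0-4 scale",
         call. = FALSE)
  }
  structure(list(family = "rating_cutoff", cutoff = as.integer(cutoff)),
            class = "binarization_spec")
}

#' @rdname binarization_spec
#' @export
ratio_scheme <- function(type = c("chance", "twice_chance", "fixed"),
                         p = NULL) {
  type <- match.arg(type)
  if (type == "fixed") {
    if (is.null(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
      stop("fixed ratio baseline p must lie in (0, 1)", call. = FALSE)
    }
  } else if (!is.null(p)) {
    stop("p is only meaningful for type = \"fixed\"", call. = FALSE)
  }
  structure(list(family = "ratio", type = type, p = p),
            class = "binarization_spec")
}

#' @rdname binarization_spec
#' @export
frequency_scheme <- function(rule = c("half_median", "percentile", "fixed"),
                             q = NULL, k = NULL) {
  rule <- match.arg(rule)
  if (rule == "percentile") {
    if (is.null(q) || length(q) != 1 || !is.finite(q) || q <= 0 || q >= 100) {
      stop("percentile q must lie in (0, 100)", call. = FALSE)
    }
  }
  if (rule == "fixed") {
    if (is.null(k) || length(k) != 1 || !is.finite(k) || k < 0) {
      stop("fixed frequency cutoff k must be a nonnegative number",
           call. = FALSE)
    }
  }
  structure(list(family = "frequency", rule = rule, q = q, k = k),
            class = "binarization_spec")
}

#' @export
print.binarization_spec <- function(x, ...) {
  cat("binarization_spec:", scheme_label(x), "\n")
  invisible(x)
}

#' Short label for a binarization scheme
#'
#' @param spec a [binarization spec][rating_scheme] or `"native"`.
#' @return a single string, e.g. `"rating>=2"`, `"ratio_twice_chance"`,
#'   `"freq_p90"`.
#' @export
scheme_label <- function(spec) {
  if (is.character(spec)) return(spec)
  switch(spec$family,
    rating_cutoff = paste0("rating>=", spec$cutoff),
    ratio = if (spec$type == "fixed") {
      sprintf("ratio_fixed_%g", spec$p)
    } else paste0("ratio_", spec$type),
    frequency = switch(spec$rule,
      half_median = "freq_half_median",
      percentile = sprintf("freq_p%g", spec$q),
      fixed = sprintf("freq_fixed_%g", spec$k)))
}

#' The researcher-network schemes conventionally compared
#'
#' The three ratio thresholds (chance, twice-chance, fixed 5%) and three
#' frequency thresholds (half-median, 75th and 90th percentile).
#'
#' @return named list of [binarization specs][rating_scheme].
#' @export
default_researcher_schemes <- function() {
  specs <- list(
    ratio_scheme("chance"),
    ratio_scheme("twice_chance"),
    ratio_scheme("fixed", p = 0.05),
    frequency_scheme("half_median"),
    frequency_scheme("percentile", q = 75),
    frequency_scheme("percentile", q = 90)
  )
  names(specs) <- vapply(specs, scheme_label, character(1))
  specs
}

#' Chance-level ratio threshold
#'
#' `1/(n_eff - 1)`: the share of a child's interactions a single classmate
#' would receive if interactions were spread uniformly over the other
#' `n_eff - 1` children. For an effective classroom size of 16 this is
#' 1/15 = 6.7%.
#'
#' @param n_eff effective classroom size (consented children), `>= 2`.
#' @return proportion in `(0, 1]`.
#' @export
chance_threshold <- function(n_eff) {
  if (length(n_eff) != 1 || !is_wholenumber(n_eff) || n_eff < 2) {
    stop("effective classroom size must be an integer >= 2", call. = FALSE)
  }
  1 / (n_eff - 1)
}

#' Binarize a teacher-rating network
#'
#' Tie present when `rating >= cutoff` ("at or above"). With `cutoff = 0`
#' every dyad is tied; symmetric input yields symmetric output.
#'
#' @param net a [value_network()] of kind `"rating"`.
#' @param cutoff integer cutoff in `0:4`.
#' @return a symmetric [binary_network()] carrying the scheme.
#' @export
binarize_rating <- function(net, cutoff) {
  if (!inherits(net, "value_network") || net$kind != "rating") {
    stop("binarize_rating expects a rating network", call. = FALSE)
  }
  spec <- rating_scheme(cutoff)
  ties <- (net$values >= spec$cutoff) * 1
  diag(ties) <- 0
  binary_network(ties, net$roster, scheme = spec, directed = FALSE)
}

#' Row-normalized interaction ratios
#'
#' Divides each observed frequency `f[i, j]` by child i's total observed
#' interactions with all classmates, giving the share of i's interaction
#' budget directed at j. Rows are normalized independently, so ratios are
#' asymmetric in general even from symmetric counts. Children with zero
#' observed interactions get an all-zero row and are listed in
#' `undefined_rows`.
#'
#' @param net a [value_network()] of kind `"count"`.
#' @return An object of class `"ratio_network"` with fields `ratios`
#'   (n x n matrix), `undefined_rows` (character vector of child ids), and
#'   `roster`.
#' @export
ratio_matrix <- function(net) {
  if (!inherits(net, "value_network") || net$kind != "count") {
    stop("ratio_matrix expects a count network", call. = FALSE)
  }
  f <- net$values
  diag(f) <- 0
  totals <- rowSums(f)
  ratios <- f / ifelse(totals == 0, 1, totals)
  undefined <- net$roster$child_ids[totals == 0]
  structure(
    list(ratios = ratios, undefined_rows = undefined, roster = net$roster),
    class = "ratio_network"
  )
}

#' @export
print.ratio_network <- function(x, ...) {
  cat("ratio_network over", nrow(x$ratios), "children;",
      length(x$undefined_rows), "undefined rows\n")
  invisible(x)
}

#' Binarize a count network by interaction-share ratio
#'
#' Computes the [ratio_matrix()] and ties the ordered dyad (i, j) when i's
#' share of interactions directed at j is at or above the baseline:
#' chance level `1/(n_eff - 1)`, twice the chance level, or a fixed
#' proportion. The comparison is inclusive ("at or above"). Output is
#' directed: row normalization breaks the symmetry of the counts, and no
#' automatic symmetrization is applied. Children with no observed
#' interactions produce no outgoing ties (reported via a message).
#'
#' @param net a [value_network()] of kind `"count"`.
#' @param scheme a [ratio_scheme()], or a string naming its type.
#' @param p fixed baseline, used when `scheme = "fixed"`.
#' @return a directed [binary_network()].
#' @export
binarize_ratio <- function(net, scheme = c("chance", "twice_chance", "fixed"),
                           p = NULL) {
  if (!inherits(scheme, "binarization_spec")) {
    scheme <- ratio_scheme(match.arg(scheme), p = p)
  }
  if (scheme$family != "ratio") {
    stop("binarize_ratio expects a ratio scheme", call. = FALSE)
  }
  rn <- ratio_matrix(net)
  n_eff <- effective_size(net)
  threshold <- switch(scheme$type,
    chance = chance_threshold(n_eff),
    twice_chance = 2 * chance_threshold(n_eff),
    fixed = scheme$p)
  ties <- (rn$ratios >= threshold - 1e-12) * 1
  diag(ties) <- 0
  if (length(rn$undefined_rows)) {
    message("children with zero observed interactions (no outgoing ties): ",
            paste(rn$undefined_rows, collapse = ", "))
  }
  binary_network(ties, net$roster, scheme = scheme, directed = TRUE)
}

#' Frequency cutoff for a count network
#'
#' The cutoff implied by a frequency rule, computed over the distribution
#' of interaction frequencies among all possible unordered pairs in the
#' network (zero-count pairs included, each pair counted once):
#' `half_median` returns half the median; `percentile(q)` returns the
#' nearest-rank `q`-th percentile (the `ceiling(q * m / 100)`-th order
#' statistic, which is always an observed — hence integer — frequency);
#' `fixed(k)` returns `k`.
#'
#' @param net a [value_network()] of kind `"count"`.
#' @param rule a [frequency_scheme()], or a string naming its rule.
#' @inheritParams frequency_scheme
#' @return a single numeric cutoff.
#' @export
frequency_cutoff <- function(net, rule = c("half_median", "percentile",
                                           "fixed"), q = NULL, k = NULL) {
  if (!inherits(rule, "binarization_spec")) {
    rule <- frequency_scheme(match.arg(rule), q = q, k = k)
  }
  if (rule$family != "frequency") {
    stop("frequency_cutoff expects a frequency scheme", call. = FALSE)
  }
  if (!inherits(net, "value_network") || net$kind != "count") {
    stop("frequency_cutoff expects a count network", call. = FALSE)
  }
  freqs <- pair_values(net$values)
  switch(rule$rule,
    half_median = 0.5 * stats::median(freqs),
    percentile = {
      m <- length(freqs)
      sort(freqs)[max(1L, ceiling(rule$q * m / 100))]
    },
    fixed = rule$k)
}

#' Binarize a count network by raw interaction frequency
#'
#' Applies [frequency_cutoff()] and ties a pair when its frequency clears
#' the cutoff. The half-median rule is strict ("above half of the
#' median"): `f > cutoff`; percentile and fixed rules are inclusive:
#' `f >= cutoff`. On integer counts with a median of 1 the half-median
#' rule ties exactly the pairs observed interacting at least once. Output
#' is symmetric.
#'
#' @inheritParams frequency_cutoff
#' @return a symmetric [binary_network()] carrying the scheme.
#' @export
binarize_frequency <- function(net, rule = c("half_median", "percentile",
                                             "fixed"), q = NULL, k = NULL) {
  if (!inherits(rule, "binarization_spec")) {
    rule <- frequency_scheme(match.arg(rule), q = q, k = k)
  }
  cutoff <- frequency_cutoff(net, rule)
  ties <- if (rule$rule == "half_median") (net$values > cutoff) * 1
          else (net$values >= cutoff) * 1
  diag(ties) <- 0
  binary_network(ties, net$roster, scheme = rule, directed = FALSE)
}

#' Binarize a valued network with any scheme
#'
#' Dispatches to [binarize_rating()], [binarize_ratio()] or
#' [binarize_frequency()] according to the spec's family.
#'
#' @param net a [value_network()].
#' @param spec a [binarization spec][rating_scheme].
#' @return a [binary_network()].
#' @export
binarize <- function(net, spec) {
  if (!inherits(spec, "binarization_spec")) {
    stop("spec must be a binarization_spec", call. = FALSE)
  }
  switch(spec$family,
    rating_cutoff = binarize_rating(net, spec$cutoff),
    ratio = binarize_ratio(net, spec),
    frequency = binarize_frequency(net, spec))
}

#' Serialize / deserialize a binarization spec
#'
#' Plain-list form for YAML/JSON config files, e.g.
#' `list(family = "ratio", type = "twice_chance")` or
#' `list(family = "frequency", rule = "percentile", q = 90)`.
#'
#' @param spec a [binarization spec][rating_scheme].
#' @param x a plain list as produced by `spec_to_list()`.
#' @return `spec_to_list()` a plain list; `spec_from_list()` a
#'   `binarization_spec`.
#' @export
spec_to_list <- function(spec) {
  unclass(spec)[!vapply(unclass(spec), is.null, logical(1))]
}

#' @rdname spec_to_list
#' @export
spec_from_list <- function(x) {
  switch(x$family,
    rating_cutoff = rating_scheme(x$cutoff),
    ratio = ratio_scheme(x$type, p = x$p),
    frequency = frequency_scheme(x$rule, q = x$q, k = x$k),
    stop("unknown binarization family: ", x$family, call. = FALSE))
}
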