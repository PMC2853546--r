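#' Normalize a raw score against its k-subset extrema
#'
#' `(raw - lo) / (hi - lo)`, the normalized score used for both diversity
#' and connectivity: 0 means the region attains the theoretical minimum
#' for its sample size, 1 the maximum.  When the range is degenerate
#' (`hi == lo`, e.g. a region containing every haplotype) the score is
#' defined as 0.
#'
#' @param raw observed score, must lie in `[lo, hi]`.
#' @param lo,hi extremal scores over all subsets of the same size.
#' @return a number in `[0, 1]`.
#' @examples
#' normalize_score(14, 3, 25)  # 0.50
#' @export
normalize_score <- function(raw, lo, hi) {
  stopifnot(is.numeric(raw), is.numeric(lo), is.numeric(hi))
  tol <- 1e-9 * (1 + abs(hi) + abs(lo))
  if (any(lo > hi + tol))
    stop("score minimum exceeds maximum", call. = FALSE)
  if (any(raw < lo - tol) || any(raw > hi + tol))
    stop("raw score ", format(raw), " outside its extremal range [",
         format(lo), ", ", format(hi), "]", call. = FALSE)
  out <- ifelse(hi - lo <= tol, 0, (raw - lo) / (hi - lo))
  pmin(1, pmax(0, out))
}

#' Read or build a region table
#'
#' A region table maps each geographic region to the set of haplotype
#' labels found there.  A haplotype may occur in several regions;
#' multiplicities are deliberately ignored -- what matters is *which*
#' haplotypes occur where, not how often.
#'
#' @param assignments data frame with columns `haplotype_id` and `region`
#'   (one row per occurrence), or a named list of label vectors.
#' @return named list of class `region_table`: region name -> unique
#'   haplotype labels.
#' @export
region_table <- function(assignments) {
  if (is.data.frame(assignments)) {
    if (ncol(assignments) < 2L)
      stop("region assignments need columns haplotype_id, region",
           call. = FALSE)
    regions <- split(as.character(assignments[[1L]]),
                     as.character(assignments[[2L]]))
  } else if (is.list(assignments)) {
    regions <- lapply(assignments, as.character)
  } else {
    stop("expected a data frame or a named list", call. = FALSE)
  }
  regions <- lapply(regions, unique)
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("every region needs a name", call. = FALSE)
  if (any(lengths(regions) == 0L))
    stop("region subsets must be non-empty", call. = FALSE)
  structure(regions, class = "region_table")
}

#' Score geographic regions by diversity and haplotype connectivity
#'
#' For every region the raw diversity (PD from the phylogeny, or AD from
#' the distance matrix) and the raw haplotype connectivity HC are
#' computed for the haplotypes found there, together with the exact
#' minimum and maximum each score can attain over *all* subsets of the
#' full haplotype set of the same size, and the resulting normalized
#' scores.  Extrema are computed once per distinct region size and
#' cached.  Rows are ordered by normalized diversity (descending, ties
#' broken by region name), so the regions worth interpreting -- the
#' high-diversity ones -- come first.
#'
#' @inheritParams threshold_graph
#' @param regions a [region_table()] (or something coercible).
#' @param diversity `"PD"` (needs `phylogeny`) or `"AD"`.
#' @param phylogeny a [haplo_net()] tree; required for PD.  If supplied
#'   without `D`, phyletic distances are derived from it.
#' @param ad_exponent exponent for [ad()] (default 2).
#' @param ... further arguments passed to [ad_extrema()] (e.g. `cap`).
#' @return data frame of class `region_scores` with columns `region`,
#'   `n`, `div`, `div_min`, `div_max`, `div_norm`, `hc`, `hc_min`,
#'   `hc_max`, `hc_norm`; attribute `diversity` records the measure used.
#' @examples
#' sim <- simulate_scenario("melting_pot", seed = 1)
#' score_regions(sim$distances, sim$regions, diversity = "PD",
#'               phylogeny = sim$phylogeny)
#' @export
score_regions <- function(D = NULL, regions, diversity = c("PD", "AD"),
                          phylogeny = NULL, ad_exponent = 2, ...) {
  diversity <- match.arg(diversity)
  if (diversity == "PD") {
    if (is.null(phylogeny))
      stop("diversity = \"PD\" requires a phylogeny", call. = FALSE)
    phylogeny <- as_haplo_net(phylogeny)
    if (!phylogeny$is_tree)
      stop("PD requires a tree phylogeny", call. = FALSE)
    if (is.null(D)) D <- phyletic_distances(phylogeny)
  }
  if (is.null(D))
    stop("a distance matrix is required (or derivable from a phylogeny)",
         call. = FALSE)
  D <- as_haplo_dist(D)
  if (!inherits(regions, "region_table")) regions <- region_table(regions)
  for (r in names(regions)) resolve_subset(D, regions[[r]])
  if (diversity == "PD") {
    extra <- setdiff(rownames(D), haplotype_labels(phylogeny))
    if (length(extra))
      stop("haplotypes absent from the phylogeny: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }

  sizes <- sort(unique(lengths(regions)))
  hc_bounds <- connectivity_bounds(D, k = sizes)
  rownames(hc_bounds) <- as.character(hc_bounds$k)
  div_bounds <- lapply(stats::setNames(sizes, sizes), function(k) {
    if (diversity == "PD")
      c(lo = pd_min(phylogeny, k), hi = pd_max(phylogeny, k))
    else if (k < 2L)
      c(lo = 0, hi = 0)
    else
      c(lo = ad_extrema(D, k, "min", exponent = ad_exponent, ...),
        hi = ad_extrema(D, k, "max", exponent = ad_exponent, ...))
  })

  rows <- lapply(names(regions), function(r) {
    Y <- regions[[r]]
    n <- length(Y)
    div <- if (diversity == "PD") pd(phylogeny, Y)
           else ad(D, Y, exponent = ad_exponent)
    db <- div_bounds[[as.character(n)]]
    hb <- hc_bounds[as.character(n), ]
    hc <- haplotype_connectivity(D, Y)
    data.frame(region = r, n = n,
               div = div, div_min = db[["lo"]], div_max = db[["hi"]],
               div_norm = normalize_score(div, db[["lo"]], db[["hi"]]),
               hc = hc, hc_min = hb$hc_min, hc_max = hb$hc_max,
               hc_norm = normalize_score(hc, hb$hc_min, hb$hc_max))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$div_norm, out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diversity") <- diversity
  class(out) <- c("region_scores", class(out))
  out
}

#' @export
print.region_scores <- function(x, digits = 2, ...) {
  cat("Region scores (diversity measure: ",
      attr(x, "diversity") %||% "?", ")\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round_half_up(v, digits))
  print(y, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up to match conventional table display (R's round() halves
# to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Annotate scored regions as hot-spot-like or melting-pot-like
#'
#' A qualitative reading of a [score_regions()] table.  The
#' connectivity signal is only meaningful where diversity is high (low
#' diversity forces low connectivity), so only regions at or above the
#' chosen quantile of normalized diversity are assessed: those with
#' normalized connectivity at or above `hc_cut` are annotated
#' `"melting-pot-like"` (divergent haplotype groups in secondary
#' contact), the rest `"hot-spot-like"` (haplotypes dispersed by in-situ
#' diversification).  All other regions get
#' `"low-diversity (not assessed)"`.  The cuts are advisory conventions,
#' not tests of significance.
#'
#' @param rows a `region_scores` data frame.
#' @param diversity_quantile quantile of `div_norm` above which regions
#'   are assessed (default 0.5, the median).
#' @param hc_cut normalized-connectivity cut separating the two verdicts.
#' @return `rows` with an extra `annotation` column.
#' @export
interpret_regions <- function(rows, diversity_quantile = 0.5,
                              hc_cut = 0.5) {
  if (!is.data.frame(rows) || !all(c("div_norm", "hc_norm") %in% names(rows)))
    stop("expected a region_scores data frame", call. = FALSE)
  if (nrow(rows) < 1L) stop("no regions to interpret", call. = FALSE)
  cut_div <- stats::quantile(rows$div_norm, probs = diversity_quantile,
                             names = FALSE)
  assessed <- rows$div_norm >= cut_div
  rows$annotation <- "low-diversity (not assessed)"
  rows$annotation[assessed & rows$hc_norm >= hc_cut] <- "melting-pot-like"
  rows$annotation[assessed & rows$hc_norm < hc_cut] <- "hot-spot-like"
  rows
}
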