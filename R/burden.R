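#' Extend test regions to the training-bin length
#'
#' For the optimal scheme, each region is widened to a window of exactly the
#' training length `l` centred at the region midpoint, shifted (not
#' truncated) to stay within its chromosome, so fresh covariates can be
#' computed at full training resolution.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param bin_length Training bin length `l`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Tibble of extended windows (`chrom`, `start`, `end`), one per
#'   input region, each of width `bin_length`.
#' @export
extend_region <- function(regions, bin_length, chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), chrom_sizes[[1]])
  }
  len <- chrom_sizes[regions$chrom]
  if (any(is.na(len))) {
    stop("regions on chromosomes absent from `chrom_sizes`", call. = FALSE)
  }
  if (any(len < bin_length)) {
    stop("chromosome shorter than the training bin length", call. = FALSE)
  }
  mid <- floor((regions$start + regions$end) / 2)
  start <- mid - floor(bin_length / 2)
  start <- pmax(0, pmin(start, len - bin_length))
  tibble::tibble(chrom = regions$chrom, start = start,
                 end = start + bin_length)
}

#' Nearest usable training bin for each region
#'
#' Returns the usable bin whose centre is closest to each region's midpoint;
#' exact ties are broken toward the lower-coordinate bin. Basis of the fast
#' approximation scheme, which reuses the training-bin prediction instead of
#' recomputing covariates.
#'
#' @param regions Region tibble.
#' @param bins Bin tibble with `usable` flags.
#' @return Integer vector of bin ids (`bins$bin`), one per region.
#' @export
nearest_training_bin <- function(regions, bins) {
  usable <- dplyr::filter(bins, .data$usable)
  out <- integer(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    rb <- which(regions$chrom == chrom)
    ub <- usable[usable$chrom == chrom, ]
    if (nrow(ub) == 0) {
      stop("no usable training bin on chromosome ", chrom, call. = FALSE)
    }
    centers <- (ub$start + ub$end) / 2
    mid <- (regions$start[rb] + regions$end[rb]) / 2
    idx <- findInterval(mid, centers)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(ub))
    # strict inequality keeps the lower bin on exact ties
    pick <- ifelse(idx == 0, hi,
                   ifelse(mid - centers[lo] <= centers[hi] - mid, lo, hi))
    out[rb] <- ub$bin[pick]
  }
  out
}

#' Region-level negative binomial parameters
#'
#' Computes `(mu_k, sigma_k)` for each test region: the bin-scale mean is
#' either copied from the nearest usable training bin's prediction
#' (`scheme = "approx"`, the production default) or freshly predicted from
#' covariates of the `l`-length extended window (`scheme = "optimal"`), and
#' then scaled by `l_k / l` to the region's length. `sigma` is taken from
#' the model unadjusted: under the mixture interpretation it measures
#' population heterogeneity, not length.
#'
#' Multi-interval regions (e.g. merged exons of one gene, sharing a `name`)
#' use the summed interval length as `l_k` and the midpoint of the bounding
#' span as the covariate anchor.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, optional `name`).
#' @param model Fitted [fit_nb_regression()] object.
#' @param bins Training-bin tibble; the model's `fitted` values must align
#'   with the usable bins in order.
#' @param scheme `"approx"` or `"optimal"`.
#' @param pca,tracks,sequences,chrom_sizes Required for the optimal scheme:
#'   the training [fit_pca()] object and the raw covariate sources used to
#'   build the training matrix. If unavailable the function falls back to
#'   the approximation with a warning.
#'
#' @return Tibble: `name`, `chrom`, `start`, `end`, `length`, `source_bin`
#'   (id or `"extended"`), `mu` and `sigma`.
#' @export
region_params <- function(regions, model, bins,
                          scheme = c("approx", "optimal"),
                          pca = NULL, tracks = NULL, sequences = NULL,
                          chrom_sizes = NULL) {
  scheme <- match.arg(scheme)
  regions <- normalize_regions(regions)
  spans <- regions %>%
    dplyr::group_by(.data$name) %>%
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      length = sum(.data$end - .data$start),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) %>%
    dplyr::select("name", "chrom", "start", "end", "length") %>%
    dplyr::arrange(.data$chrom, .data$start, .data$name)
  usable <- dplyr::filter(bins, .data$usable)
  stopifnot(nrow(usable) == length(model$fitted))
  l <- usable$end[1] - usable$start[1]

  if (scheme == "optimal" && (is.null(pca) || is.null(tracks) ||
                              is.null(chrom_sizes))) {
    warning("covariate sources unavailable for the optimal scheme; ",
            "falling back to the nearest-bin approximation", call. = FALSE)
    scheme <- "approx"
  }
  if (scheme == "approx") {
    nb <- nearest_training_bin(spans, bins)
    pos <- match(nb, usable$bin)
    mu_bin <- model$fitted[pos]
    sigma <- if (model$constant_sigma) rep(model$sigma, nrow(spans)) else
      model$sigma[pos]
    source_bin <- as.character(nb)
  } else {
    ext <- extend_region(spans, l, chrom_sizes)
    ext$usable <- TRUE
    ext$bin <- seq_len(nrow(ext))
    cov <- build_covariates(ext, tracks, sequences)
    scores <- project_pca(pca, cov)
    mu_bin <- predict(model, scores)
    sigma <- if (model$constant_sigma) rep(model$sigma, nrow(spans)) else {
      exp(drop(cbind(1, scores) %*% model$alpha))
    }
    source_bin <- rep("extended", nrow(spans))
  }
  spans %>%
    dplyr::mutate(
      source_bin = source_bin,
      mu = mu_bin * .data$length / l,
      sigma = sigma
    )
}

normalize_regions <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (!"name" %in% names(regions)) {
    regions$name <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  }
  regions
}

#' Count variants per region and disease
#'
#' Half-open intersection of the variant catalog with (possibly
#' multi-interval) regions, pooled over samples. A variant in two intervals
#' of the same region counts once.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, `name`).
#' @param variants Variant tibble (`chrom`, `pos`, `sample`, `disease`).
#' @return Tibble `name`, `disease`, `y` with zeros kept.
#' @export
count_region_mutations <- function(regions, variants) {
  regions <- normalize_regions(regions)
  gr <- regions_to_granges(regions)
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(vr, gr)
  assigned <- tibble::tibble(
    name = regions$name[S4Vectors::subjectHits(hits)],
    disease = variants$disease[S4Vectors::queryHits(hits)],
    sample = variants$sample[S4Vectors::queryHits(hits)],
    pos = variants$pos[S4Vectors::queryHits(hits)],
    chrom = variants$chrom[S4Vectors::queryHits(hits)]
  ) %>%
    dplyr::distinct()  # one hit per variant per region
  tidyr::expand_grid(name = unique(regions$name),
                     disease = sort(unique(variants$disease))) %>%
    dplyr::left_join(dplyr::count(assigned, .data$name, .data$disease,
                                  name = "y"),
                     by = c("name", "disease")) %>%
    dplyr::mutate(y = dplyr::coalesce(.data$y, 0L))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (`p_(i) * K / i` with
#' cumulative-minimum enforcement), input order preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` is an error.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NA p-values are not allowed", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Combine p-values across diseases with Fisher's method
#'
#' `T = -2 * sum(log p_d)` referred to the upper tail of a chi-square with
#' `2 D` degrees of freedom. Assumes the per-disease tests are independent.
#' Zeros (or values below `1e-300`) are floored at `1e-300` and flagged;
#' missing values are skipped with the degrees of freedom reduced
#' accordingly.
#'
#' @param p Vector of per-disease p-values for one region.
#' @return A one-row tibble: `statistic` (T), `df`, `p_value`,
#'   `n_combined`, `n_floored`.
#' @export
fisher_combine <- function(p) {
  keep <- !is.na(p)
  p <- p[keep]
  if (length(p) == 0) {
    stop("no p-values to combine", call. = FALSE)
  }
  stopifnot(all(p >= 0 & p <= 1))
  floored <- p < 1e-300
  p <- pmax(p, 1e-300)
  t_stat <- -2 * sum(log(p))
  tibble::tibble(
    statistic = t_stat,
    df = 2 * length(p),
    p_value = stats::pchisq(t_stat, df = 2 * length(p), lower.tail = FALSE),
    n_combined = length(p),
    n_floored = sum(floored)
  )
}

#' Burden test of target regions against the fitted background model
#'
#' The end-to-end region test: region parameters via [region_params()],
#' observed counts via [count_region_mutations()], one-sided upper-tail
#' p-values via [nb_tail_pvalue()], and BH adjustment within disease (and
#' within annotation `class`, when the regions carry one).
#'
#' @inheritParams region_params
#' @param variants Variant catalog tibble.
#' @param diseases Optional subset of diseases to test.
#' @return A `burden_result` tibble: one row per region x disease with
#'   `name`, `class` (if given), `chrom`, `start`, `end`, `length`,
#'   `disease`, `y`, `mu`, `sigma`, `p`, `p_bh`.
#' @export
burden_test <- function(regions, variants, model, bins,
                        scheme = c("approx", "optimal"),
                        pca = NULL, tracks = NULL, sequences = NULL,
                        chrom_sizes = NULL, diseases = NULL) {
  regions <- normalize_regions(regions)
  params <- region_params(regions, model, bins, scheme = scheme, pca = pca,
                          tracks = tracks, sequences = sequences,
                          chrom_sizes = chrom_sizes)
  counts <- count_region_mutations(regions, variants)
  if (!is.null(diseases)) {
    counts <- dplyr::filter(counts, .data$disease %in% diseases)
  }
  classes <- if ("class" %in% names(regions)) {
    dplyr::distinct(regions, .data$name, .data$class)
  } else {
    dplyr::distinct(regions["name"]) %>% dplyr::mutate(class = "region")
  }
  res <- params %>%
    dplyr::inner_join(counts, by = "name") %>%
    dplyr::inner_join(classes, by = "name") %>%
    dplyr::mutate(p = nb_tail_pvalue(.data$y, .data$mu, .data$sigma)) %>%
    dplyr::group_by(.data$disease, .data$class) %>%
    dplyr::mutate(p_bh = bh_adjust(.data$p)) %>%
    dplyr::ungroup() %>%
    dplyr::select("name", "class", "chrom", "start", "end", "length",
                  "disease", "y", "mu", "sigma", "p", "p_bh") %>%
    dplyr::arrange(.data$disease, .data$chrom, .data$start, .data$name)
  class(res) <- c("burden_result", class(res))
  res
}

#' Combine a burden result across diseases
#'
#' Applies [fisher_combine()] per region to the per-disease p-values of a
#' [burden_test()] result and BH-adjusts the combined p-values (within
#' annotation class).
#'
#' @param result A `burden_result` tibble.
#' @return Tibble: `name`, `class`, `chrom`, `start`, `end`, `statistic`,
#'   `df`, `p_value`, `p_bh`, `n_combined`, `n_floored`.
#' @export
combine_diseases <- function(result) {
  result %>%
    dplyr::group_by(.data$name, .data$class, .data$chrom, .data$start,
                    .data$end) %>%
    dplyr::reframe(fisher_combine(.data$p)) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(p_bh = bh_adjust(.data$p_value)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$chrom, .data$start, .data$name)
}

#' Pathway burden from per-gene p-values
#'
#' Fisher combination across the `M` member genes of each gene set
#' (chi-square with `2 M` degrees of freedom), BH-adjusted across pathways
#' within each disease. Members without a p-value (absent from the tested
#' annotation) are dropped and counted; an empty pathway is skipped with a
#' warning.
#'
#' @param gene_sets Tibble with columns `set` and `gene` (see
#'   [read_gmt()]), or a named list of gene vectors.
#' @param gene_p Tibble with columns `name` (gene), `disease`, `p` —
#'   typically a [burden_test()] result.
#' @return Tibble: `set`, `disease`, `n_members`, `n_dropped`, `statistic`,
#'   `p_value`, `p_bh`.
#' @export
network_pvalue <- function(gene_sets, gene_p) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- purrr::imap_dfr(gene_sets, ~ tibble::tibble(set = .y,
                                                             gene = .x))
  }
  sizes <- dplyr::count(gene_sets, .data$set, name = "size")
  res <- gene_sets %>%
    dplyr::inner_join(gene_p, by = c(gene = "name"),
                      relationship = "many-to-many") %>%
    dplyr::group_by(.data$set, .data$disease) %>%
    dplyr::reframe(fisher_combine(.data$p)) %>%
    dplyr::left_join(sizes, by = "set") %>%
    dplyr::mutate(n_members = .data$n_combined,
                  n_dropped = .data$size - .data$n_combined)
  empty <- setdiff(sizes$set, res$set)
  if (length(empty) > 0) {
    warning("pathway(s) with no testable member skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  res %>%
    dplyr::group_by(.data$disease) %>%
    dplyr::mutate(p_bh = bh_adjust(.data$p_value)) %>%
    dplyr::ungroup() %>%
    dplyr::select("set", "disease", "n_members", "n_dropped", "statistic",
                  "p_value", "p_bh") %>%
    dplyr::arrange(.data$disease, .data$p_value, .data$set)
}

#' Expected-vs-observed quantile table for a Q-Q plot
#'
#' @param p Vector of p-values.
#' @return Tibble `expected`, `observed` on the -log10 scale, sorted.
#' @export
qq_table <- function(p) {
  n <- length(p)
  tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
}
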