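#' Average a genomic signal track over training bins
#'
#' Computes, for each bin, the mean per-base signal with uncovered bases
#' counted as zero ("mean0" semantics): the sum of `value * overlap_width`
#' over all track intervals intersecting the bin, divided by the bin width.
#'
#' @param track Signal track as a tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `value`, e.g. from [read_bedgraph()]. Intervals
#'   must not overlap each other.
#' @param bins Bin tibble from [make_bins()].
#'
#' @return Numeric vector, one mean per row of `bins`.
#' @export
average_signal_over_bins <- function(track, bins) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  out <- numeric(nrow(bins))
  if (nrow(track) == 0) return(out)
  extra <- setdiff(unique(track$chrom), unique(bins$chrom))
  if (length(extra) == length(unique(track$chrom))) {
    stop("track chromosomes do not match bin chromosomes: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  hits <- GenomicRanges::findOverlaps(bins_to_granges(bins),
                                      regions_to_granges(track))
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(bins$end[qi], track$end[si]) - pmax(bins$start[qi], track$start[si])
  sums <- tapply(ov * track$value[si], qi, sum)
  idx <- as.integer(names(sums))
  out[idx] <- as.numeric(sums) / (bins$end[idx] - bins$start[idx])
  out
}

#' GC fraction of each bin, ignoring ambiguous bases
#'
#' Returns (#G + #C) / (#A + #C + #G + #T) per bin, case-insensitive. Ns and
#' other ambiguity codes are excluded from the denominator; a bin with no
#' unambiguous base at all gets `NA` and should be dropped from training.
#'
#' @param sequences Named `Biostrings::DNAStringSet` (or named character
#'   vector) of full chromosome sequences, names matching `bins$chrom`.
#' @param bins Bin tibble from [make_bins()].
#'
#' @return Numeric vector in `[0, 1]`, `NA` for all-ambiguous bins.
#' @export
gc_fraction <- function(sequences, bins) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  miss <- setdiff(unique(bins$chrom), names(sequences))
  if (length(miss) > 0) {
    stop("no sequence for chromosomes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  too_short <- bins$end > Biostrings::width(sequences)[match(bins$chrom, names(sequences))]
  if (any(too_short)) {
    stop("sequence shorter than bin on: ",
         paste(unique(bins$chrom[too_short]), collapse = ", "), call. = FALSE)
  }
  views <- Biostrings::DNAStringSet(purrr::pmap_chr(
    list(bins$chrom, bins$start, bins$end),
    function(chrom, start, end) as.character(
      Biostrings::subseq(sequences[[chrom]], start + 1, end))
  ))
  freq <- Biostrings::letterFrequency(views, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  ifelse(denom == 0, NA_real_, (freq[, "G"] + freq[, "C"]) / denom)
}

#' Assemble the bin-by-feature covariate matrix
#'
#' Averages each signal track over the usable bins and optionally appends GC
#' content, yielding the covariate table that the background-rate regression
#' is trained on. Bins with missing GC (all-ambiguous sequence) are marked
#' unusable and excluded.
#'
#' @param bins Bin tibble (only `usable` rows are used).
#' @param tracks Named list of signal-track tibbles; replicate tracks whose
#'   names share a prefix before `".rep"` are averaged first.
#' @param sequences Optional chromosome sequences for a `gc` feature.
#'
#' @return Tibble with `bin` followed by one column per feature.
#' @export
build_covariates <- function(bins, tracks, sequences = NULL) {
  usable <- dplyr::filter(bins, .data$usable)
  stopifnot(length(tracks) == 0 || !is.null(names(tracks)))
  base <- sub("\\.rep[0-9]+$", "", names(tracks))
  feats <- purrr::map(split(seq_along(tracks), base), function(idx) {
    rowMeans(vapply(tracks[idx],
                    function(t) average_signal_over_bins(t, usable),
                    numeric(nrow(usable))))
  })
  out <- tibble::as_tibble(feats)[, unique(base), drop = FALSE]
  out <- dplyr::bind_cols(tibble::tibble(bin = usable$bin), out)
  if (!is.null(sequences)) {
    out$gc <- gc_fraction(sequences, usable)
    if (anyNA(out$gc)) {
      warning(sum(is.na(out$gc)),
              " bin(s) with no unambiguous sequence dropped", call. = FALSE)
      out <- dplyr::filter(out, !is.na(.data$gc))
    }
  }
  out
}

#' Principal component analysis of the covariate matrix
#'
#' Centers and scales every feature (sample SD, n - 1 denominator) and
#' rotates to principal axes, retaining all components: genomic covariates
#' are strongly collinear, and regressing on the full orthogonal basis
#' avoids multicollinearity without discarding signal. Constant columns are
#' dropped with a warning (scaling is undefined). For reproducibility across
#' linear-algebra backends each loading column is sign-fixed so that its
#' largest-magnitude element is positive.
#'
#' @param x Covariate tibble from [build_covariates()] (a `bin` column, if
#'   present, is carried through as row identity), or a numeric matrix.
#'
#' @return An object of class `covariate_pca` with elements `center`,
#'   `scale`, `rotation`, `sdev`, `explained_variance_ratio`, `scores`
#'   (n x m matrix `X'`), `features`, `dropped`, `bin`.
#' @export
fit_pca <- function(x) {
  bin <- NULL
  if (is.data.frame(x)) {
    if ("bin" %in% names(x)) {
      bin <- x$bin
      x <- dplyr::select(x, -"bin")
    }
    x <- as.matrix(x)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("non-finite covariate at row ", bad[1], ", feature '",
         colnames(x)[bad[2]], "'", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant covariate column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-|loading| entry of each column positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  structure(
    list(
      center = pc$center,
      scale = pc$scale,
      rotation = pc$rotation,
      sdev = pc$sdev,
      explained_variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
      scores = pc$x,
      features = colnames(x),
      dropped = dropped,
      bin = bin
    ),
    class = "covariate_pca"
  )
}

#' @export
print.covariate_pca <- function(x, ...) {
  cat("<covariate_pca> ", nrow(x$scores), " bins x ", length(x$features),
      " features; PC1 explains ",
      sprintf("%.1f%%", 100 * x$explained_variance_ratio[1]), " of variance\n",
      sep = "")
  invisible(x)
}

#' Project new covariate rows into an existing PCA basis
#'
#' Standardizes `newdata` with the training means/SDs and applies the stored
#' rotation — used to obtain PC scores for extended test-region bins.
#'
#' @param pca A `covariate_pca` object.
#' @param newdata Tibble or matrix with the training feature columns.
#' @return Score matrix with one row per input row.
#' @export
project_pca <- function(pca, newdata) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, pca$features, drop = FALSE])
  }
  scale(newdata, center = pca$center, scale = pca$scale) %*% pca$rotation
}

#' @method tidy covariate_pca
#' @export
tidy.covariate_pca <- function(x, ...) {
  tibble::tibble(
    pc = seq_along(x$sdev),
    sdev = x$sdev,
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' Rank principal components by correlation with mutation counts
#'
#' Computes the Pearson correlation of each PC score vector with the per-bin
#' counts of each disease, then ranks PCs by the mean absolute correlation
#' across diseases. Used to pick the top-k PCs for reduced regressions.
#'
#' @param scores Score matrix `X'` (rows aligned with the counts' bins) or a
#'   `covariate_pca` object.
#' @param counts Counts tibble from [count_mutations()] restricted to the
#'   same bins, or a disease-by-bin matrix.
#'
#' @return Tibble with one row per (PC, disease): `pc`, `disease`, `rho`,
#'   plus the per-PC `mean_abs_rho` and dense `rank` (1 = most correlated).
#' @export
rank_pcs <- function(scores, counts) {
  if (inherits(scores, "covariate_pca")) scores <- scores$scores
  if (is.data.frame(counts)) counts <- counts_matrix(counts)
  stopifnot(ncol(counts) == nrow(scores))
  if (any(apply(counts, 1, stats::sd) == 0)) {
    stop("zero-variance count vector: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(scores, t(counts))  # m x D
  long <- tibble::as_tibble(rho, .name_repair = "minimal") %>%
    stats::setNames(rownames(counts)) %>%
    dplyr::mutate(pc = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"pc", names_to = "disease", values_to = "rho")
  long %>%
    dplyr::group_by(.data$pc) %>%
    dplyr::mutate(mean_abs_rho = mean(abs(.data$rho))) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$mean_abs_rho))) %>%
    dplyr::arrange(.data$rank, .data$pc, .data$disease)
}
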