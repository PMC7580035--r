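#' Partition a genome into fixed-length training bins
#'
#' Divides each chromosome into consecutive, non-overlapping bins of exactly
#' `bin_length` base pairs, starting at coordinate 0. A trailing remainder
#' shorter than `bin_length` is discarded: the burden model assumes a constant
#' training-bin length, and region-level means are later rescaled by
#' `l_k / l` against that length.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp, or a
#'   two-column data frame (`chrom`, `size`) as read by [read_chrom_sizes()].
#' @param bin_length Bin length `l` in bp (default 1 Mb, the production
#'   resolution for whole-genome burden analysis).
#' @param human If `TRUE`, keep only autosomes and chrX (drop chrY and
#'   unplaced contigs) to avoid sex imbalance in counts and covariates.
#'   Synthetic genomes keep every declared chromosome.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `bin` (integer id, genome-wide) and `usable` (all `TRUE` until
#'   [apply_blacklist()] is run).
#' @export
make_bins <- function(chrom_sizes, bin_length = 1e6, human = FALSE) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), chrom_sizes[[1]])
  }
  if (length(chrom_sizes) == 0) {
    stop("`chrom_sizes` is empty", call. = FALSE)
  }
  if (!is.numeric(bin_length) || length(bin_length) != 1 || bin_length <= 0) {
    stop("`bin_length` must be a single positive number", call. = FALSE)
  }
  if (any(chrom_sizes <= 0)) {
    stop("all chromosome lengths must be positive", call. = FALSE)
  }
  if (human) {
    keep <- grepl("^(chr)?([0-9]+|X)$", names(chrom_sizes))
    chrom_sizes <- chrom_sizes[keep]
    if (length(chrom_sizes) == 0) {
      stop("no autosomal or chrX chromosomes after applying the human filter",
           call. = FALSE)
    }
  }
  n_per_chrom <- floor(chrom_sizes / bin_length)
  if (all(n_per_chrom == 0)) {
    warning("`bin_length` exceeds every chromosome length; no bins produced",
            call. = FALSE)
  }
  bins <- purrr::map2_dfr(names(chrom_sizes), n_per_chrom, function(chrom, k) {
    if (k == 0) return(NULL)
    tibble::tibble(
      chrom = chrom,
      start = bin_length * (seq_len(k) - 1),
      end   = bin_length * seq_len(k)
    )
  })
  bins %>%
    dplyr::mutate(bin = dplyr::row_number(), usable = TRUE)
}

bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end)
  )
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
}

#' Flag bins overlapping blacklist or assembly-gap intervals as unusable
#'
#' Any bin overlapping a mappability-excludable or assembly-gap interval by
#' at least 1 bp is removed from training (`usable = FALSE`) — the strictest
#' reading of blacklist filtering; no partial-overlap threshold is applied.
#'
#' @param bins Bin tibble from [make_bins()].
#' @param blacklist,gaps Interval tibbles (`chrom`, `start`, `end`; 0-based
#'   half-open, e.g. from [read_bed()]), or `NULL`.
#'
#' @return `bins` with the `usable` column updated.
#' @export
apply_blacklist <- function(bins, blacklist = NULL, gaps = NULL) {
  bad <- dplyr::bind_rows(blacklist, gaps)
  if (is.null(bad) || nrow(bad) == 0) {
    return(bins)
  }
  hits <- GenomicRanges::findOverlaps(
    bins_to_granges(bins), regions_to_granges(bad), minoverlap = 1L
  )
  bins$usable[unique(S4Vectors::queryHits(hits))] <- FALSE
  bins
}

#' Tabulate pooled mutation counts per disease and per bin
#'
#' Assigns each variant to the bin with `start <= pos < end` and pools counts
#' over samples within each disease, giving the disease-by-bin count matrix
#' that the negative binomial regression is trained on. Variants falling in
#' unusable bins, in discarded remainder regions, or on chromosomes without
#' bins are dropped and reported.
#'
#' Duplicate calls at the same position in the same sample are counted once;
#' the same position mutated in different samples counts once per sample
#' (the pooled model counts events per sample).
#'
#' @param variants Tibble with columns `chrom`, `pos` (0-based), `sample`,
#'   `disease` (see [read_variants()]).
#' @param bins Bin tibble from [make_bins()] / [apply_blacklist()].
#' @param per_sample If `TRUE`, also return per-sample counts.
#'
#' @return A tibble with columns `disease`, `bin`, `y` covering every usable
#'   bin x disease combination (zeros included). Attributes: `dropped`, a
#'   per-disease tibble of dropped-variant counts; `per_sample`, the
#'   per-sample count tibble when requested.
#' @export
count_mutations <- function(variants, bins, per_sample = FALSE) {
  stopifnot(all(c("chrom", "pos", "sample", "disease") %in% names(variants)))
  variants <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$sample,
                              .data$disease)
  usable <- dplyr::filter(bins, .data$usable)
  missing_chrom <- setdiff(unique(variants$chrom), unique(bins$chrom))
  if (length(missing_chrom) > 0) {
    warning("variants on chromosomes without bins were dropped: ",
            paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  # locate each variant's usable bin (start <= pos < end, half-open)
  lookup <- usable %>%
    dplyr::transmute(.data$chrom, .data$start, last = .data$end - 1, .data$bin)
  joined <- variants %>%
    dplyr::left_join(
      lookup,
      by = dplyr::join_by("chrom", dplyr::between(x$pos, y$start, y$last))
    )
  dropped <- joined %>%
    dplyr::filter(is.na(.data$bin)) %>%
    dplyr::count(.data$disease, name = "dropped")
  assigned <- dplyr::filter(joined, !is.na(.data$bin))
  grid <- tidyr::expand_grid(
    disease = sort(unique(variants$disease)),
    bin = usable$bin
  )
  counts <- assigned %>%
    dplyr::count(.data$disease, .data$bin, name = "y") %>%
    dplyr::right_join(grid, by = c("disease", "bin")) %>%
    dplyr::mutate(y = dplyr::coalesce(.data$y, 0L)) %>%
    dplyr::arrange(.data$disease, .data$bin)
  if (per_sample) {
    ps <- assigned %>%
      dplyr::count(.data$disease, .data$sample, .data$bin, name = "y")
    attr(counts, "per_sample") <- ps
  }
  attr(counts, "dropped") <- dropped
  counts
}

#' Counts tibble to a disease-by-bin matrix
#'
#' @param counts Output of [count_mutations()].
#' @return Integer matrix, rows = diseases, columns = bins (named by bin id).
#' @export
counts_matrix <- function(counts) {
  wide <- tidyr::pivot_wider(counts, names_from = "bin", values_from = "y")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$disease
  m
}
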