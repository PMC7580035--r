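#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-separated file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  stats::setNames(x$size, x$chrom)
}

#' Read a BED3/BED4 interval file
#'
#' @param path Path to a BED file (0-based half-open; optional 4th name
#'   column). Malformed lines raise an error naming the line number.
#' @return Tibble `chrom`, `start`, `end` (+ `name` if present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(nf < 3 | is.na(start) | is.na(end) | end < start)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path, call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = vapply(parts, `[`, "", 1),
    start = start, end = end
  )
  if (all(nf >= 4)) out$name <- vapply(parts, `[`, "", 4)
  out
}

#' Write intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name` (or
#'   `bin`, used as the name for training bins).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  name <- if ("name" %in% names(x)) x$name else if ("bin" %in% names(x))
    x$bin else NULL
  df <- as.data.frame(x[cols])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  if (!is.null(name)) df$name <- name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    value = gr$score
  )
}

#' Read a somatic variant catalog
#'
#' Two dialects: a 4-column tab-separated table (`chrom`, 1-based `pos`,
#' `sample`, `disease`) or a VCF, whose 1-based positions are converted to
#' the internal 0-based convention. For VCF input, sample and disease are
#' supplied by the caller; FILTER is ignored unless `pass_only = TRUE`.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"tabular"` or `"vcf"`.
#' @param sample,disease Labels for VCF input (single strings).
#' @param pass_only Keep only `FILTER == PASS` VCF records?
#' @return Tibble `chrom`, `pos` (0-based), `sample`, `disease`.
#' @export
read_variants <- function(path, format = c("auto", "tabular", "vcf"),
                          sample = "sample1", disease = "disease1",
                          pass_only = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tabular"
  }
  if (format == "tabular") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "pos", "sample", "disease"),
                           colClasses = c("character", "numeric", "character",
                                          "character"))
    return(tibble::tibble(chrom = x$chrom, pos = x$pos - 1,
                          sample = x$sample, disease = x$disease))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = 7, dimnames = list(NULL, colnames(fx)))
  keep <- if (pass_only) !is.na(fx[, "FILTER"]) & fx[, "FILTER"] == "PASS" else
    rep(TRUE, nrow(fx))
  tibble::tibble(
    chrom = fx[keep, "CHROM"],
    pos = as.numeric(fx[keep, "POS"]) - 1,
    sample = sample,
    disease = disease
  )
}

#' Read gene-set definitions from a GMT file
#'
#' @param path GMT path: set name, description, then member genes,
#'   tab-separated.
#' @return Tibble `set`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) {
      stop("GMT line with fewer than three fields", call. = FALSE)
    }
    tibble::tibble(set = f[1], gene = f[-(1:2)])
  })
}

#' Read transcripts of known protein-coding genes from a GTF
#'
#' Imports a GENCODE-dialect GTF and keeps transcript records of
#' protein-coding genes; when a `gene_status` attribute exists, only
#' `KNOWN` genes are retained (newer annotation releases drop the
#' attribute, in which case the filter is skipped with a warning).
#' Coordinates are converted from 1-based closed to 0-based half-open.
#'
#' @param path GTF path.
#' @param feature Which records define the intervals: `"transcript"`
#'   (default) or `"CDS"`.
#' @return Tibble `gene`, `transcript`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gtf_genes <- function(path, feature = c("transcript", "CDS")) {
  feature <- match.arg(feature)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type == feature
  if (!is.null(meta$gene_type)) {
    keep <- keep & meta$gene_type == "protein_coding"
  }
  if (!is.null(meta$gene_status)) {
    keep <- keep & (is.na(meta$gene_status) | meta$gene_status == "KNOWN")
  } else {
    warning("annotation has no gene_status attribute; KNOWN filter skipped",
            call. = FALSE)
  }
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  name <- if (!is.null(meta$gene_name)) meta$gene_name else meta$gene_id
  tibble::tibble(
    gene = as.character(name),
    transcript = as.character(meta$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Merge a gene's transcripts into a non-overlapping interval union
#'
#' Overlapping or abutting transcript intervals of each gene are collapsed
#' (half-open union), giving one merged multi-interval region per gene for
#' coding burden tests. Genes with zero transcripts are skipped with a
#' warning.
#'
#' @param transcripts Tibble from [read_gtf_genes()] (columns `gene`,
#'   `chrom`, `start`, `end`).
#' @return Tibble `name` (gene), `chrom`, `start`, `end` — sorted,
#'   non-overlapping intervals per gene.
#' @export
merge_transcripts <- function(transcripts) {
  empty <- unique(transcripts$gene[is.na(transcripts$start)])
  if (length(empty) > 0) {
    warning("gene(s) without transcripts skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
    transcripts <- dplyr::filter(transcripts, !is.na(.data$start))
  }
  transcripts %>%
    dplyr::group_by(name = .data$gene, .data$chrom) %>%
    dplyr::reframe(merge_intervals(.data$start, .data$end)) %>%
    dplyr::arrange(.data$chrom, .data$start, .data$name)
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {        # overlap or half-open abutment
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Derive strand-aware promoter and TSS windows
#'
#' Windows strictly upstream of (and excluding) the first transcribed base
#' of each transcript: on the plus strand `[start - L, start)`, on the
#' minus strand `[end, end + L)` in 0-based half-open coordinates, with
#' `L = 2500` bp for promoters and `L = 100` bp for TSS windows. Windows
#' are clipped at chromosome bounds with a warning and deduplicated across
#' transcripts sharing a start site.
#'
#' @param transcripts Tibble from [read_gtf_genes()].
#' @param promoter_len,tss_len Upstream window lengths in bp.
#' @param chrom_sizes Optional named vector for right-end clipping.
#' @return A list of two region tibbles, `promoters` and `tss`, each with
#'   `name` (gene), `chrom`, `start`, `end`.
#' @export
derive_promoters_tss <- function(transcripts, promoter_len = 2500,
                                 tss_len = 100, chrom_sizes = NULL) {
  stopifnot(all(transcripts$strand %in% c("+", "-")))
  upstream <- function(L) {
    w <- transcripts %>%
      dplyr::mutate(
        w_start = ifelse(.data$strand == "+", .data$start - L, .data$end),
        w_end = ifelse(.data$strand == "+", .data$start, .data$end + L)
      )
    if (any(w$w_start < 0)) {
      warning("window(s) clipped at chromosome start", call. = FALSE)
      w$w_start <- pmax(0, w$w_start)
    }
    if (!is.null(chrom_sizes)) {
      lim <- chrom_sizes[w$chrom]
      if (any(w$w_end > lim, na.rm = TRUE)) {
        warning("window(s) clipped at chromosome end", call. = FALSE)
        w$w_end <- pmin(w$w_end, lim)
      }
    }
    w %>%
      dplyr::filter(.data$w_end > .data$w_start) %>%
      dplyr::distinct(name = .data$gene, .data$chrom, start = .data$w_start,
                      end = .data$w_end) %>%
      dplyr::arrange(.data$chrom, .data$start, .data$name)
  }
  list(promoters = upstream(promoter_len), tss = upstream(tss_len))
}

#' Intersect two region sets
#'
#' Returns the elements of `a` that overlap an element of `b` by at least
#' 1 bp (`mode = "overlap"`) or lie entirely within one (`mode =
#' "within"`). Supports promoter-by-DHS-by-TFBS style screening chains.
#'
#' @param a,b Region tibbles (`chrom`, `start`, `end`, ...).
#' @param mode `"overlap"` or `"within"`.
#' @return The qualifying rows of `a`.
#' @export
intersect_regions <- function(a, b, mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, ])
  hits <- GenomicRanges::findOverlaps(
    regions_to_granges(a), regions_to_granges(b),
    type = if (mode == "within") "within" else "any", minoverlap = 1L
  )
  a[sort(unique(S4Vectors::queryHits(hits))), ]
}

#' Write / read a burden result table
#'
#' Tab-separated rendering of a [burden_test()] or [combine_diseases()]
#' table with deterministic row order (chrom, start, name) and p-values in
#' scientific notation with six significant digits.
#'
#' @param x Result tibble.
#' @param path Output path.
#' @return `path` invisibly (write); the table as a tibble (read).
#' @export
write_result_table <- function(x, path) {
  ord_cols <- intersect(c("chrom", "start", "name"), names(x))
  x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(ord_cols)))
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 6, format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Serialize / restore a fitted model as a versioned JSON archive
#'
#' Stores the regression coefficients, overdispersion, feature order, the
#' PCA reference (means, scales, rotation, variance ratios) and the
#' training bin length in a plain-text archive, so that trained models can
#' be reused across sessions and machines.
#'
#' @param model An `nb_regression` fit.
#' @param pca The training `covariate_pca` object (optional).
#' @param bin_length Training bin length `l`.
#' @param path Output path (JSON).
#' @return `path` invisibly (write); a list `model`, `pca`, `bin_length`
#'   (read).
#' @export
write_model <- function(model, path, pca = NULL, bin_length = NULL) {
  payload <- list(
    format_version = 1L,
    beta = as.list(model$beta),
    alpha = as.list(model$alpha),
    sigma = model$sigma,
    constant_sigma = model$constant_sigma,
    loglik = model$loglik,
    converged = model$converged,
    fitted = model$fitted,
    y = model$y,
    bin_length = bin_length,
    pca = if (!is.null(pca)) list(
      center = as.list(pca$center), scale = as.list(pca$scale),
      rotation = pca$rotation, sdev = pca$sdev, features = pca$features
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(
    list(
      beta = unlist(p$beta), alpha = unlist(p$alpha), sigma = p$sigma,
      constant_sigma = p$constant_sigma, fitted = p$fitted,
      loglik = p$loglik, converged = p$converged, y = p$y,
      n = length(p$fitted), n_iter = NA_integer_,
      se_beta = rep(NA_real_, length(p$beta))
    ),
    class = "nb_regression"
  )
  pca <- NULL
  if (!is.null(p$pca)) {
    rot <- as.matrix(p$pca$rotation)
    rownames(rot) <- p$pca$features
    pca <- structure(
      list(
        center = unlist(p$pca$center), scale = unlist(p$pca$scale),
        rotation = rot, sdev = p$pca$sdev,
        explained_variance_ratio = p$pca$sdev^2 / sum(p$pca$sdev^2),
        scores = NULL, features = p$pca$features, dropped = character(0),
        bin = NULL
      ),
      class = "covariate_pca"
    )
  }
  list(model = model, pca = pca, bin_length = p$bin_length)
}
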