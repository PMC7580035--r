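test_that("extend_region centres an l-window and shifts at chromosome ends", {
  sizes <- c(chrA = 10e6)
  r <- tibble::tibble(chrom = "chrA",
                      start = c(4e6, 0, 10e6 - 1000),
                      end = c(4e6 + 2000, 1000, 10e6))
  ext <- extend_region(r, 1e6, sizes)
  expect_true(all(ext$end - ext$start == 1e6))
  # interior region: window centred on the midpoint
  expect_equal(ext$start[1], 4e6 + 1000 - 5e5)
  # left edge: shifted, not truncated
  expect_equal(ext$start[2], 0)
  # right edge: shifted back inside
  expect_equal(ext$end[3], 10e6)
  expect_error(extend_region(r, 20e6, sizes), "shorter")
  expect_error(extend_region(dplyr::mutate(r, chrom = "nope"), 1e6, sizes),
               "absent")
})

test_that("nearest_training_bin picks the closest usable centre, lower tie", {
  bins <- make_bins(c(chrA = 4e6), 1e6)  # centres at 0.5, 1.5, 2.5, 3.5 Mb
  r <- tibble::tibble(chrom = "chrA",
                      start = c(0, 9e5, 3.9e6),
                      end = c(1e3, 1.1e6, 4e6))
  expect_equal(nearest_training_bin(r, bins), c(1L, 1L, 4L))
  # exact tie at 1.0 Mb midpoint -> lower bin
  tie <- tibble::tibble(chrom = "chrA", start = 1e6 - 500, end = 1e6 + 500)
  expect_equal(nearest_training_bin(tie, bins), 1L)
  # unusable bins are skipped in favour of the nearest usable one
  bins2 <- bins
  bins2$usable[1] <- FALSE
  expect_equal(nearest_training_bin(r, bins2), c(2L, 2L, 4L))
  bad <- dplyr::mutate(bins, usable = FALSE)
  expect_error(nearest_training_bin(r, bad), "no usable")
})

fit_toy_model <- function(n = 200, seed = 13, sigma = 0.2) {
  set.seed(seed)
  bins <- make_bins(c(chrA = n / 2 * 1e6, chrB = n / 2 * 1e6), 1e6)
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f1"))
  mu <- exp(4 + 0.5 * x[, 1])
  y <- sample_gamma_poisson(n, mu, sigma)
  list(bins = bins, x = x, y = y, mu = mu,
       model = fit_nb_regression(x, y))
}

test_that("region_params scales the bin mean by length and keeps sigma", {
  toy <- fit_toy_model()
  # region exactly equal to training bin 3: both schemes must agree exactly
  b3 <- toy$bins[3, ]
  r <- tibble::tibble(chrom = b3$chrom, start = b3$start, end = b3$end,
                      name = "whole_bin")
  p <- region_params(r, toy$model, toy$bins)
  expect_equal(p$mu, toy$model$fitted[3])
  expect_equal(p$sigma, toy$model$sigma)
  expect_equal(p$source_bin, "3")

  # a 10 kb sub-region of bin 3: mu scales by 10e3 / 1e6
  r2 <- tibble::tibble(chrom = b3$chrom, start = b3$start + 2e5,
                       end = b3$start + 2.1e5, name = "sub")
  p2 <- region_params(r2, toy$model, toy$bins)
  expect_equal(p2$mu, toy$model$fitted[3] * 1e4 / 1e6)
  expect_equal(p2$length, 1e4)

  # multi-interval region: summed length, one row out
  r3 <- tibble::tibble(chrom = b3$chrom,
                       start = b3$start + c(0, 5e5),
                       end = b3$start + c(1e4, 5.2e5),
                       name = "gene1")
  p3 <- region_params(r3, toy$model, toy$bins)
  expect_equal(nrow(p3), 1)
  expect_equal(p3$length, 3e4)
  expect_equal(p3$mu, toy$model$fitted[3] * 3e4 / 1e6)

  # optimal scheme without covariate sources falls back with a warning
  expect_warning(
    pf <- region_params(r, toy$model, toy$bins, scheme = "optimal"),
    "falling back"
  )
  expect_equal(pf$mu, p$mu)
})

test_that("region counting pools samples and dedups within a region", {
  r <- tibble::tibble(chrom = "chrA",
                      start = c(100, 500), end = c(300, 700),
                      name = c("g1", "g1"))
  v <- tibble::tibble(
    chrom = "chrA",
    pos = c(150, 299, 300, 600, 600),
    sample = c("s1", "s1", "s1", "s1", "s2"),
    disease = c("d1", "d1", "d1", "d1", "d2")
  )
  cnt <- count_region_mutations(r, v)
  # half-open: pos 300 is outside [100, 300); both intervals pool into g1
  expect_equal(cnt$y[cnt$name == "g1" & cnt$disease == "d1"], 3L)
  expect_equal(cnt$y[cnt$name == "g1" & cnt$disease == "d2"], 1L)

  # zero rows are kept for regions with no variants
  r2 <- dplyr::bind_rows(r, tibble::tibble(chrom = "chrA", start = 1e6,
                                           end = 1e6 + 100, name = "empty"))
  cnt2 <- count_region_mutations(r2, v)
  expect_equal(cnt2$y[cnt2$name == "empty"], c(0L, 0L))

  # a variant inside two overlapping intervals of one region counts once
  r3 <- tibble::tibble(chrom = "chrA", start = c(100, 120),
                       end = c(200, 220), name = c("g1", "g1"))
  v3 <- tibble::tibble(chrom = "chrA", pos = 150, sample = "s1",
                       disease = "d1")
  expect_equal(count_region_mutations(r3, v3)$y, 1L)
})

test_that("BH adjustment reproduces the step-up worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 1.0)), c(0.002, 1.0))
  # order preservation
  p <- c(0.04, 0.001, 0.9)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_equal(order(bh_adjust(p)), order(p))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
})

test_that("Fisher combination matches the closed form and a chi-square oracle", {
  f <- fisher_combine(c(0.5, 0.5))
  expect_equal(f$statistic, -4 * log(0.5))
  expect_equal(round(f$statistic, 4), 2.7726)
  expect_equal(round(f$p_value, 4), 0.5966)
  expect_equal(f$df, 4)

  # D = 1 is the identity map
  expect_equal(fisher_combine(0.37)$p_value, 0.37, tolerance = 1e-12)

  # oracle: survival of chi-square(2D) by numeric quadrature of its density
  p3 <- c(0.01, 0.2, 0.6)
  t3 <- -2 * sum(log(p3))
  quad <- integrate(function(u) dchisq(u, df = 6), t3, Inf,
                    rel.tol = 1e-12)$value
  expect_equal(fisher_combine(p3)$p_value, quad, tolerance = 1e-9)

  # NA skipped with df reduction; zero floored and flagged
  fna <- fisher_combine(c(0.5, NA, 0.5))
  expect_equal(fna$df, 4)
  expect_equal(fna$n_combined, 2)
  f0 <- fisher_combine(c(0, 0.5))
  expect_equal(f0$n_floored, 1)
  expect_gt(f0$p_value, 0)
  expect_error(fisher_combine(NA_real_), "no p-values")
})

test_that("Fisher combination of independent uniforms is itself uniform", {
  set.seed(31)
  p <- replicate(4000, fisher_combine(runif(3))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("burden_test flags an injected hotspot and little else", {
  toy <- fit_toy_model(n = 200, seed = 17)
  set.seed(18)
  regions <- sample_regions(toy$bins, 60, len_range = c(4e4, 8e4))
  # background variants at each region's own fitted rate
  params <- region_params(regions, toy$model, toy$bins)
  bg_y <- sample_gamma_poisson(nrow(params), params$mu, toy$model$sigma)
  idx <- rep.int(seq_len(nrow(params)), bg_y)
  variants <- tibble::tibble(
    chrom = params$chrom[idx],
    pos = params$start[idx] +
      floor(runif(length(idx)) * (params$end[idx] - params$start[idx])),
    sample = "s1", disease = "d1"
  )
  # inject a 10x burst into the first region
  hot <- params[params$name == regions$name[1], ]
  extra <- round(9 * hot$mu)
  variants <- dplyr::bind_rows(variants, tibble::tibble(
    chrom = hot$chrom,
    pos = hot$start + floor(runif(extra) * (hot$end - hot$start)),
    sample = "s1", disease = "d1"
  ))
  res <- burden_test(regions, variants, toy$model, toy$bins)
  expect_s3_class(res, "burden_result")
  expect_equal(nrow(res), 60)
  hit <- res[res$name == regions$name[1], ]
  expect_lt(hit$p_bh, 0.01)
  expect_lt(sum(res$p_bh < 0.1), 5)
  # p-values consistent with their own (y, mu, sigma) columns
  expect_equal(res$p, nb_tail_pvalue(res$y, res$mu, res$sigma))
})

test_that("combine_diseases reduces a two-disease result via Fisher", {
  toy <- fit_toy_model(n = 100, seed = 23)
  set.seed(24)
  regions <- sample_regions(toy$bins, 10)
  params <- region_params(regions, toy$model, toy$bins)
  variants <- purrr::map_dfr(c("d1", "d2"), function(d) {
    y <- rpois(nrow(params), params$mu)
    idx <- rep.int(seq_len(nrow(params)), y)
    tibble::tibble(
      chrom = params$chrom[idx],
      pos = params$start[idx] +
        floor(runif(length(idx)) * (params$end[idx] - params$start[idx])),
      sample = "s1", disease = d
    )
  })
  res <- burden_test(regions, variants, toy$model, toy$bins)
  comb <- combine_diseases(res)
  expect_equal(nrow(comb), 10)
  expect_true(all(comb$n_combined == 2))
  expect_true(all(comb$df == 4))
  # spot-check one region against a direct fisher_combine call
  nm <- comb$name[1]
  expect_equal(comb$p_value[comb$name == nm],
               fisher_combine(res$p[res$name == nm])$p_value)
})

test_that("network p-values combine member genes per pathway", {
  gene_p <- tibble::tibble(
    name = c("g1", "g2", "g3"),
    disease = "d1",
    p = c(0.5, 0.5, 0.01)
  )
  # M = 1: combination is the gene's own p-value
  r1 <- network_pvalue(list(solo = "g3"), gene_p)
  expect_equal(r1$p_value, 0.01, tolerance = 1e-12)
  expect_equal(r1$n_members, 1)

  # M = 2 with (0.5, 0.5): the documented closed form
  r2 <- network_pvalue(list(pair = c("g1", "g2")), gene_p)
  expect_equal(round(r2$p_value, 4), 0.5966)

  # member missing from the tested annotation is dropped and counted
  r3 <- network_pvalue(list(px = c("g1", "g2", "absent")), gene_p)
  expect_equal(r3$n_members, 2)
  expect_equal(r3$n_dropped, 1)

  # empty pathway skipped with a warning; BH across pathways per disease
  expect_warning(
    r4 <- network_pvalue(list(a = "g3", b = c("g1", "g2"), z = "nothing"),
                         gene_p),
    "skipped.*z"
  )
  expect_equal(nrow(r4), 2)
  expect_equal(r4$p_bh, bh_adjust(r4$p_value))
})

test_that("pathway combination of uniform gene p-values is uniform", {
  set.seed(41)
  n_path <- 10000
  gene_p <- tibble::tibble(
    name = paste0("g", seq_len(3 * n_path)),
    disease = "d1",
    p = runif(3 * n_path)
  )
  sets <- tibble::tibble(
    set = rep(paste0("path", seq_len(n_path)), each = 3),
    gene = gene_p$name
  )
  res <- network_pvalue(sets, gene_p)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("qq_table pairs sorted observations with uniform quantiles", {
  q <- qq_table(c(0.5, 0.01, 0.9))
  expect_equal(q$observed, -log10(c(0.01, 0.5, 0.9)))
  expect_equal(q$expected, -log10((1:3 - 0.5) / 3))
})
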