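make_pseudobulk <- function(n_samples = 6, n_genes = 20, seed = 51) {
  set.seed(seed)
  X <- matrix(rgamma(n_samples * n_genes, 2, 0.1), n_samples, n_genes,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("g%02d", seq_len(n_genes))))
  X
}

test_that("scores span exactly 0-10 and the cutoff is the healthy maximum", {
  X <- make_pseudobulk()
  sig <- c("g01", "g05", "g09")
  sc <- inflammation_score(X, sig, healthy_ids = c("s01", "s02"))
  expect_equal(min(sc$score), 0)
  expect_equal(max(sc$score), 10)
  cutoff <- attr(sc, "cutoff")
  expect_equal(cutoff, max(sc$score[sc$is_healthy]))
  expect_false(any(sc$score[sc$is_healthy] > cutoff))
})

test_that("the score is invariant to per-sample monotone transforms", {
  X <- make_pseudobulk()
  sig <- c("g02", "g07", "g13", "g19")
  base <- inflammation_score(X, sig, healthy_ids = "s01")
  Xt <- X
  Xt[1, ] <- exp(X[1, ] / max(X[1, ]))       # different monotone map per sample
  Xt[2, ] <- X[2, ]^3
  Xt[3, ] <- rank(X[3, ])
  trans <- inflammation_score(Xt, sig, healthy_ids = "s01")
  expect_equal(trans$raw, base$raw, tolerance = 1e-12)
  expect_equal(trans$score, base$score, tolerance = 1e-12)
})

test_that("identical samples score identically and top-loaded samples hit 10", {
  X <- make_pseudobulk(n_samples = 4)
  X[2, ] <- X[1, ]
  sig <- c("g03", "g04")
  sc <- inflammation_score(X, sig, healthy_ids = "s04")
  expect_equal(sc$raw[1], sc$raw[2], tolerance = 1e-12)
  ## force the signature genes to occupy the top ranks of sample 3
  X[3, ] <- seq_len(ncol(X))
  X[3, c("g03", "g04")] <- c(1000, 999)
  sc2 <- inflammation_score(X, sig, healthy_ids = "s04")
  expect_equal(which.max(sc2$raw), 3L)
  expect_equal(sc2$score[3], 10)
})

test_that("the running sum matches an independent brute-force oracle", {
  ## independent implementation: walk the ranked gene list explicitly
  oracle_es <- function(expr, sig_genes, alpha = 0.25) {
    r <- rank(expr, ties.method = "average")
    ord <- names(sort(r, decreasing = TRUE))
    n <- length(expr)
    n_sig <- sum(names(expr) %in% sig_genes)
    denom_in <- sum(r[names(expr) %in% sig_genes]^alpha)
    p_in <- 0; p_out <- 0; es <- 0
    for (g in ord) {
      if (g %in% sig_genes) p_in <- p_in + r[[g]]^alpha / denom_in
      else p_out <- p_out + 1 / (n - n_sig)
      es <- es + (p_in - p_out)
    }
    es
  }
  X <- make_pseudobulk(n_samples = 6, n_genes = 20, seed = 99)
  sig <- c("g01", "g06", "g11", "g16")
  sc <- inflammation_score(X, sig, healthy_ids = "s01")
  for (i in seq_len(nrow(X))) {
    e <- X[i, ]
    expect_equal(sc$raw[i], oracle_es(e, sig), tolerance = 1e-10)
  }
})

test_that("degenerate signatures are rejected", {
  X <- make_pseudobulk()
  expect_error(inflammation_score(X, c("nope1", "nope2"), "s01"),
               "no genes")
  expect_error(inflammation_score(X, character(0), "s01"), "non-empty")
  expect_error(inflammation_score(X, colnames(X), "s01"), "every measured")
  expect_error(inflammation_score(X[1, , drop = FALSE], "g01", "s01"),
               "2 samples")
  expect_error(inflammation_score(X, "g01", "zz"), "healthy_ids")
})

test_that("signature files round-trip in plain and GMT form", {
  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("IL1B", "CXCL8", "S100A8"), plain)
  expect_equal(read_signature(plain), c("IL1B", "CXCL8", "S100A8"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("inflam\tdesc\tIL1B\tCXCL8", gmt)
  expect_equal(read_signature(gmt), c("IL1B", "CXCL8"))
})

test_that("CD remission applies the two-of-three rule with escalation override", {
  expect_true(classify_remission_cd(4, TRUE, 1))       # 2 of 3
  expect_false(classify_remission_cd(7, TRUE, 3))      # 0 of 3
  expect_false(classify_remission_cd(2, FALSE, 0, escalated = TRUE))
  ## boundaries: HBI 5 just fails, Nancy 1 just passes
  expect_true(classify_remission_cd(5, FALSE, 1))      # 2 of 3
  expect_false(classify_remission_cd(5, TRUE, 2))      # 0 of 3
  expect_true(is.na(classify_remission_cd(NA, TRUE, 1)))
  expect_error(classify_remission_cd(-1, FALSE, 0), "non-negative")
})

test_that("UC remission applies the two-of-three rule with escalation override", {
  expect_true(classify_remission_uc(2, 1, 2))          # SSCAI + UCEIS
  expect_false(classify_remission_uc(5, 4, 2))
  expect_true(classify_remission_uc(3, 1, 1))          # UCEIS + Nancy
  expect_false(classify_remission_uc(2, 1, 0, escalated = TRUE))
  expect_error(classify_remission_uc(2, -1, 0), "non-negative")
})

test_that("remission calls are monotone: worsening an index never helps", {
  grid <- expand.grid(hbi = c(0, 4, 5, 9), ulcers = c(FALSE, TRUE),
                      nancy = 0:4)
  calls <- with(grid, classify_remission_cd(hbi, ulcers, nancy))
  worse <- with(grid, classify_remission_cd(hbi + 2, ulcers | TRUE, nancy + 1))
  expect_false(any(!calls & worse))
  ugrid <- expand.grid(sscai = c(0, 2, 3, 8), uceis = c(0, 1, 2, 6),
                       nancy = 0:4)
  ucalls <- with(ugrid, classify_remission_uc(sscai, uceis, nancy))
  uworse <- with(ugrid, classify_remission_uc(sscai + 1, uceis + 1, nancy + 1))
  expect_false(any(!ucalls & uworse))
})

test_that("the pattern decision table is total and matches hand enumeration", {
  combos <- expand.grid(
    baseline_diff = c("higher_in_R", "higher_in_NR", "none"),
    change_R = c("up", "down", "none"),
    change_NR = c("up", "down", "none"),
    stringsAsFactors = FALSE)
  got <- classify_pattern(combos$baseline_diff, combos$change_R,
                          combos$change_NR)
  ## independent hand-derived lookup (precedence 3, 1, 4, 5, 6, 2)
  expected_one <- function(b, cr, cn) {
    if (b == "higher_in_R" && cr == "down") return("3")
    if (b == "none" && cr == "down" && cn == "none") return("1")
    if (cr == "up" && cn == "up") return("4")
    if (cr == "up" && cn == "none") return("5")
    if (b == "none" && cr == "none" && cn == "up") return("6")
    if (cn == "down" && cr %in% c("none", "down")) return("2")
    "unclassified"
  }
  expected <- mapply(expected_one, combos$baseline_diff, combos$change_R,
                     combos$change_NR)
  expect_equal(got, unname(expected))
  ## every pattern is reachable; unclassified is the only other value
  expect_setequal(unique(got), c(as.character(1:6), "unclassified"))
  ## spot checks straight from the taxonomy
  expect_equal(classify_pattern("none", "down", "none"), "1")
  expect_equal(classify_pattern("higher_in_R", "down", "none"), "3")
  expect_error(classify_pattern("sideways", "up", "up"), "baseline_diff")
})

test_that("abundance changes are detected with direction on a planted shift", {
  set.seed(71)
  n_per_group <- 8
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:(2 * n_per_group)),
    patient_id = rep(sprintf("p%02d", 1:n_per_group), 2),
    timepoint = rep(c("g1_pre", "g2_post"), each = n_per_group))
  states <- c("stateA", "stateB", "stateC")
  counts <- tidyr::expand_grid(sample_id = meta$sample_id, state = states) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::mutate(count = rpois(
      dplyr::n(),
      ifelse(state == "stateA" & timepoint == "g2_post", 150, 50)))
  res <- suppressWarnings(
    abundance_change_test(counts[c("sample_id", "state", "count")], meta,
                          grouping = "timepoint"))
  a <- res[res$state == "stateA", ]
  expect_true(a$significant)
  expect_equal(a$direction, "up")   # enriched in the second sorted level
})

test_that("identical composition in both groups yields no significant state", {
  meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                         patient_id = sprintf("p%02d", 1:12),
                         group = rep(c("x", "y"), each = 6))
  counts <- tidyr::expand_grid(sample_id = meta$sample_id,
                               state = c("a", "b")) |>
    dplyr::mutate(count = rep(c(30, 70), times = 12))
  res <- suppressWarnings(
    abundance_change_test(counts, meta, grouping = "group"))
  expect_false(any(res$significant))
  ## per-sample proportions are well-formed before testing
  totals <- counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(tot = sum(count))
  expect_true(all(totals$tot == 100))
})
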