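mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(bat_id = r[[1]], tissue = r[[2]], call = r[[3]],
               site_id = if (length(r) > 3) r[[4]] else "S1",
               season = if (length(r) > 4) r[[5]] else "autumn",
               stringsAsFactors = FALSE)))
}

test_that("a bat is non-local iff any tissue call is non-local", {
  cl <- combine_tissues(mk_calls(
    list("b1", "fur", "local"), list("b1", "wing", "local"),
    list("b2", "fur", "local"), list("b2", "wing", "non-local"),
    list("b3", "wing", "non-local"),
    list("b4", "fur", "local")))
  expect_equal(cl$combined[cl$bat_id == "b1"], "local")
  expect_equal(cl$combined[cl$bat_id == "b2"], "non-local")
  expect_equal(cl$combined[cl$bat_id == "b3"], "non-local")
  expect_equal(cl$fur_call[cl$bat_id == "b3"], "missing")
  expect_equal(cl$combined[cl$bat_id == "b4"], "local")
  expect_error(combine_tissues(mk_calls(list("b", "fur", "nonsense"))),
               "unknown call")
})

test_that("flipping a tissue call to non-local never flips a bat to local", {
  set.seed(53)
  for (i in 1:20) {
    calls <- do.call(rbind, lapply(1:10, function(b) data.frame(
      bat_id = paste0("b", b), tissue = c("fur", "wing"),
      call = sample(c("local", "non-local"), 2, replace = TRUE),
      stringsAsFactors = FALSE)))
    before <- combine_tissues(calls)
    j <- sample.int(nrow(calls), 1)
    calls$call[j] <- "non-local"
    after <- combine_tissues(calls)
    was_nl <- before$bat_id[before$combined == "non-local"]
    expect_true(all(after$combined[after$bat_id %in% was_nl] == "non-local"))
  }
})

test_that("site summaries count and partition classified bats", {
  calls <- mk_calls(
    list("b1", "fur", "local", "S1", "autumn"),
    list("b2", "fur", "local", "S1", "autumn"),
    list("b3", "fur", "local", "S1", "autumn"),
    list("b4", "fur", "non-local", "S1", "autumn"),
    list("b5", "fur", "non-local", "S2", "spring"))
  cl <- combine_tissues(calls)
  ss <- summarize_sites(cl)
  s1 <- ss[ss$site_id == "S1", ]
  expect_equal(s1$n_bats, 4)
  expect_equal(s1$prop_nonlocal, 0.25)
  expect_equal(sum(ss$n_bats), nrow(cl))

  empty <- summarize_sites(cl[0, ])
  expect_equal(nrow(empty), 0)

  # orphan classification: a classified bat absent from the bat table
  cl2 <- cl[, c("bat_id", "fur_call", "wing_call", "combined")]
  bats <- bat_rows("b1", fur = -20)
  expect_error(summarize_sites(cl2, bats), "referential-integrity")
})

test_that("site summaries match a brute-force recount on a synthetic world", {
  cfg <- synth_config(seed = 61, n_sites = 6, bats_per_site = 10)
  res <- run_world(cfg)
  ss <- summarize_sites(res$classifications)
  expect_equal(sum(ss$n_bats), length(unique(res$world$bats$bat_id)))
  # independent tally: loop over bats, count by hand
  cl <- res$classifications
  for (k in seq_len(nrow(ss))) {
    ids <- cl$bat_id[cl$site_id == ss$site_id[k] & cl$season == ss$season[k]]
    n_nl <- 0L
    for (id in ids)
      if (cl$combined[cl$bat_id == id] == "non-local") n_nl <- n_nl + 1L
    expect_equal(ss$n_bats[k], length(ids))
    expect_equal(ss$n_nonlocal[k], n_nl)
  }
})

test_that("tissue agreement counts wing non-locals and their fur matches", {
  cl <- combine_tissues(mk_calls(
    list("b1", "fur", "local", "S1", "autumn"),
    list("b1", "wing", "local", "S1", "autumn"),
    list("b2", "fur", "non-local", "S1", "autumn"),
    list("b2", "wing", "non-local", "S1", "autumn"),
    list("b3", "fur", "local", "S1", "spring"),
    list("b3", "wing", "non-local", "S1", "spring"),
    list("b4", "fur", "non-local", "S1", "spring")))  # fur-only: excluded
  ag <- tissue_agreement(cl)
  expect_equal(ag$n_wing_nonlocal, 2)
  expect_equal(ag$n_both_nonlocal, 1)
  expect_lte(ag$n_both_nonlocal, ag$n_wing_nonlocal)
  expect_equal(ag$by_season$n_both_nonlocal[ag$by_season$season == "autumn"],
               1)

  all_local <- combine_tissues(mk_calls(
    list("c1", "fur", "local"), list("c1", "wing", "local")))
  ag0 <- tissue_agreement(all_local)
  expect_equal(ag0$n_wing_nonlocal, 0)
  expect_equal(ag0$n_both_nonlocal, 0)
})

test_that("tissue agreement matches a brute-force recount on 50 bats", {
  set.seed(67)
  calls <- do.call(rbind, lapply(1:50, function(b) data.frame(
    bat_id = sprintf("b%02d", b), tissue = c("fur", "wing"),
    call = sample(c("local", "non-local"), 2, replace = TRUE, prob = c(0.7, 0.3)),
    site_id = "S1", season = sample(c("spring", "autumn"), 1),
    stringsAsFactors = FALSE)))
  ag <- tissue_agreement(combine_tissues(calls))
  n_w <- 0L; n_b <- 0L
  for (b in unique(calls$bat_id)) {
    w <- calls$call[calls$bat_id == b & calls$tissue == "wing"]
    f <- calls$call[calls$bat_id == b & calls$tissue == "fur"]
    if (w == "non-local") {
      n_w <- n_w + 1L
      if (f == "non-local") n_b <- n_b + 1L
    }
  }
  expect_equal(ag$n_wing_nonlocal, n_w)
  expect_equal(ag$n_both_nonlocal, n_b)
})

test_that("the LRT is zero when nothing is dropped and nonnegative always", {
  tab <- gen_lmm_table(71)
  f <- d2h ~ tissue + season + sex + (1 | site_id) + (1 | bat_id)
  same <- isoassign:::.lrt(f, f, tab, "nothing")
  expect_equal(same$chisq, 0, tolerance = 1e-6)
  expect_equal(same$p, 1)

  for (term in c("tissue", "season", "sex")) {
    r <- lmm_lrt(tab, term)
    expect_gte(r$chisq, 0)
    expect_equal(r$df, 1)
    expect_true(r$p >= 0 && r$p <= 1)
  }
})

test_that("a strong injected tissue offset is detected", {
  r <- lmm_lrt(gen_lmm_table(73, tissue_offset = 5), "tissue")
  expect_lt(r$p, 0.001)
})

test_that("single-tissue bats are excluded when dual_tissue_only is set", {
  tab <- gen_lmm_table(79, n_bats = 100)
  tab_plus <- rbind(tab, data.frame(
    bat_id = "EXTRA", site_id = "S01", season = "spring", sex = "male",
    tissue = "fur", d2h = 50))   # wild single-tissue outlier
  r_all <- lmm_lrt(tab_plus, "tissue", dual_tissue_only = FALSE)
  r_dual <- lmm_lrt(tab_plus, "tissue", dual_tissue_only = TRUE)
  r_base <- lmm_lrt(tab, "tissue")
  expect_equal(r_dual$chisq, r_base$chisq, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(r_all$chisq, r_base$chisq)))
})

test_that("the fur-wing difference model behaves under null and effect", {
  # constant response: no information, chisq ~ 0
  const <- data.frame(bat_id = sprintf("b%02d", 1:30),
                      site_id = rep(c("A", "B", "C"), 10),
                      season = rep(c("spring", "autumn"), 15),
                      sex = rep(c("male", "female"), 15), delta_d2h = 5)
  r0 <- delta_lmm_lrt(const, "season")
  expect_equal(r0$chisq, 0, tolerance = 1e-6)

  # type-I error at alpha 0.05 over 100 null replicates stays below 10%
  rej_null <- mean(vapply(1:100, function(s)
    delta_lmm_lrt(gen_delta_table(3000 + s), "season")$p < 0.05,
    logical(1)))
  expect_lte(rej_null, 0.10)

  # a 3 permil season shift with 2 permil residual SD is usually caught
  rej_eff <- mean(vapply(1:100, function(s)
    delta_lmm_lrt(gen_delta_table(4000 + s, season_offset = 3),
                  "season")$p < 0.05, logical(1)))
  expect_gte(rej_eff, 0.8)

  expect_error(delta_lmm_lrt(rbind(const, const), "season"),
               "one row per bat")
})
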