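make_cutoffs <- function(grip = 30, act = 20) {
  m <- matrix(c(grip, grip, rep(act, 8)), 2,
              dimnames = list(c("e4_minus", "e4_plus"),
                              c("grip", "act_phys", "act_soc", "act_integ",
                                "act_novel")))
  structure(m, class = c("ef_cutoffs", class(m)))
}

test_that("band indicators categorize per the weight table", {
  expect_equal(categorize_indicator("pp", 80), 2L)
  expect_equal(categorize_indicator("pp", 45), 0L)
  expect_equal(categorize_indicator("pp", 60), 1L)
  # band boundaries: 52 and 72 are moderate
  expect_equal(categorize_indicator("pp", c(52, 72)), c(1L, 1L))
  expect_equal(categorize_indicator("bmi", 22), 0L)
  expect_equal(categorize_indicator("bmi", 32), 2L)
  expect_equal(categorize_indicator("bmi", 27), 1L)
  # boundaries: 18.5 normal, 25 overweight, 30 overweight (not obese)
  expect_equal(categorize_indicator("bmi", c(18.5, 25, 30, 17)),
               c(0L, 1L, 1L, 1L))
  expect_equal(categorize_indicator("education", 12), 0L)
  expect_equal(categorize_indicator("education", 10), 1L)
  expect_equal(categorize_indicator("education", 6), 2L)
  expect_equal(categorize_indicator("education", c(8, 11)), c(1L, 1L))
  expect_error(categorize_indicator("nope", 1), "unknown risk indicator")
  expect_true(is.na(categorize_indicator("pp", NA)))
})

test_that("mean-split indicators use the stratum mean, ties counting as strong", {
  cut <- make_cutoffs(grip = 30, act = 20)
  expect_equal(categorize_indicator("grip", 35, cut, "e4_minus"), 0L)
  expect_equal(categorize_indicator("grip", 25, cut, "e4_minus"), 1L)
  # exactly at the mean = strong (weight 0)
  expect_equal(categorize_indicator("grip", 30, cut, "e4_plus"), 0L)
  expect_equal(categorize_indicator("act_soc", 20, cut, "e4_minus"), 0L)
  expect_error(categorize_indicator("grip", 30), "cutoffs")
})

test_that("stratified cutoffs are baseline stratum means", {
  co <- quick_cohort(n = 80, seed = 3)
  co$grip[1:2] <- c(20, 40)
  grp <- apoe_group(co$apoe)
  cut <- risk_cutoffs(co)
  for (s in c("e4_minus", "e4_plus")) {
    rows <- which(grp == s)
    expect_equal(unclass(cut)[s, "grip"], mean(co$grip[rows], na.rm = TRUE))
    expect_equal(unclass(cut)[s, "act_novel"],
                 mean(co$act_novel[rows], na.rm = TRUE))
  }
  # identical values: cutoff equals the value, everyone classified strong
  co2 <- co
  co2$grip <- 31.5
  cut2 <- risk_cutoffs(co2)
  expect_equal(unname(unclass(cut2)[, "grip"]), c(31.5, 31.5))
  expect_true(all(categorize_indicator("grip", co2$grip, cut2,
                                       "e4_minus") == 0L))
})

test_that("component scores reproduce the worked examples", {
  cut <- make_cutoffs(grip = 30, act = 20)
  expect_equal(functional_health_score(80, 25, 32, cut, "e4_minus"), 5L)
  expect_equal(functional_health_score(45, 35, 22, cut, "e4_minus"), 0L)
  expect_equal(functional_health_score(60, 35, 27, cut, "e4_minus"), 2L)
  expect_equal(lifestyle_reserve_score(15, 15, 15, 15, 6, cut, "e4_minus"), 6L)
  expect_equal(lifestyle_reserve_score(25, 25, 25, 25, 16, cut, "e4_minus"), 0L)
  expect_equal(lifestyle_reserve_score(15, 15, 25, 25, 10, cut, "e4_minus"), 3L)
  expect_equal(combined_mcrs(5L, 6L), 11L)
  expect_equal(combined_mcrs(0L, 0L), 0L)
  expect_equal(combined_mcrs(2L, 3L), 5L)
  # missing components propagate
  expect_true(is.na(functional_health_score(NA, 25, 32, cut, "e4_minus")))
  expect_true(is.na(combined_mcrs(NA_integer_, 3L)))
})

test_that("brute-force enumeration confirms score ranges", {
  rng <- enumerate_score_ranges()
  expect_equal(range(rng$frs), c(0, 5))
  expect_equal(range(rng$lrs), c(0, 6))
  expect_equal(range(rng$mcrs), c(0, 11))
  # every integer in between is attainable
  expect_setequal(unique(rng$frs), 0:5)
  expect_setequal(unique(rng$lrs), 0:6)
  expect_setequal(unique(rng$mcrs), 0:11)
})

test_that("scores are integers, conserved, and order-invariant", {
  co <- quick_cohort(n = 150, seed = 5)
  rs <- risk_scores(co)
  ok <- !is.na(rs$mcrs)
  expect_true(all(rs$mcrs[ok] == rs$frs[ok] + rs$lrs[ok]))
  expect_true(all(rs$frs[ok] %in% 0:5))
  expect_true(all(rs$lrs[!is.na(rs$lrs)] %in% 0:6))
  expect_true(all(rs$mcrs[ok] %in% 0:11))
  # permuting participants permutes the scores identically
  perm <- sample(nrow(co))
  rs_p <- risk_scores(co[perm, ])
  expect_equal(rs_p$mcrs, rs$mcrs[perm])
  # audit columns reconstruct the sums
  expect_equal(rs$frs, rs$w_pp + rs$w_grip + rs$w_bmi)
})

test_that("scores are monotone in each component's risk category", {
  cut <- make_cutoffs()
  base <- functional_health_score(45, 35, 22, cut, "e4_minus")
  worse_pp <- functional_health_score(60, 35, 22, cut, "e4_minus")
  worst_pp <- functional_health_score(80, 35, 22, cut, "e4_minus")
  expect_true(base <= worse_pp && worse_pp <= worst_pp)
  expect_gte(functional_health_score(45, 20, 22, cut, "e4_minus"), base)
  expect_gte(functional_health_score(45, 35, 32, cut, "e4_minus"), base)
})
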