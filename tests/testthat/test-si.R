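test_that("support counts reduce each event type to a/(a+b) form", {
  idx <- toy_index()
  # intron retention: a = round(mean(left, right)), b = spliced count
  ir <- detect_intron_retention(
    mk_junctions("chr1", 200, 300, count = 15),
    mk_evidence("chr1", 200, 300, "s1", left = 4, right = 6), idx)
  s <- event_support(ir, mk_junctions("chr1", 200, 300, count = 15),
                     mk_evidence("chr1", 200, 300, "s1", left = 4, right = 6),
                     "s1")
  expect_equal(c(s$a, s$b), c(5L, 15L))

  # exon skipping: a = skip count, b = round(mean(u, d))
  j <- mk_junctions("chr1", c(200, 400, 200), c(300, 500, 500),
                    count = c(10, 14, 9))
  es <- detect_exon_skipping(j, idx)
  s2 <- event_support(es, j, empty_evidence(), "s1")
  expect_equal(c(s2$a, s2$b), c(9L, 12L))

  # alternative first exon: b sums the gene's other donors
  jb <- rbind(mk_junctions("chr2", c(1100, 1250), c(1300, 1300),
                           count = c(10, 20)),
              mk_junctions("chr2", 1280, 1300, count = 30))
  afe <- detect_alt_first_exon(jb, idx)
  s3 <- event_support(afe, jb, empty_evidence(), "s1")
  this <- s3[afe$v_start == 1280, ]
  expect_equal(c(this$a, this$b), c(30L, 30L))

  # half-away-from-zero rounding of boundary means
  expect_equal(spliceIndex:::round_half_away(c(4.5, 5.5, -4.5)),
               c(5, 6, -5))
})

test_that("SI and delta-SI follow the ratio definition with a support gate", {
  expect_equal(compute_si(5, 15), 0.25)
  expect_equal(compute_si(0, 20), 0)
  expect_true(is.na(compute_si(2, 3, min_support = 10)))
  expect_equal(compute_delta_si(0.30, 0.10), 0.2)
  expect_equal(compute_delta_si(0.10, 0.30), -0.2)
  expect_true(is.na(compute_delta_si(NA_real_, 0.3)))
})

test_that("Fisher exact p-values match the hypergeometric oracle", {
  expect_equal(test_event(5, 5, 5, 5), 1)
  expect_equal(test_event(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(test_event(0, 0, 3, 7), 1)   # degenerate margin

  set.seed(1)
  for (i in 1:200) {
    tab <- as.integer(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
    p_impl <- test_event(tab[1], tab[2], tab[3], tab[4])
    p_orac <- oracle_fisher(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p_impl, p_orac, tolerance = 1e-9)
  }
})

test_that("BH q-values match the naive quadratic definition", {
  expect_equal(adjust_fdr(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(numeric(0)), numeric(0))

  set.seed(2)
  for (i in 1:25) {
    p <- runif(sample(1:400, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("significance requires both the delta-SI and the FDR gate", {
  idx <- plain_index()
  mk <- function(a_c, b_c, a_t, b_t) {
    rbind(mk_junctions("chr1", c(200, 250), c(400, 400), sample_id = "ctl",
                       count = c(b_c, a_c)),
          mk_junctions("chr1", c(200, 250), c(400, 400), sample_id = "trt",
                       count = c(b_t, a_t)))
  }
  j <- mk(10, 90, 30, 70)    # SI 0.10 -> 0.30
  ev <- detect_alt_ss(j, idx, "5SS", control = "ctl")
  cl <- call_events(ev, j, empty_evidence(), "ctl", "trt")
  expect_equal(cl$si_control, 0.10)
  expect_equal(cl$si_treated, 0.30)
  expect_equal(cl$delta_si, 0.20)
  expect_lt(cl$q_value, 0.01)
  expect_true(cl$significant)
  expect_equal(cl$direction, "up")

  # FDR gate alone fails the call
  cl2 <- call_events(ev, j, empty_evidence(), "ctl", "trt",
                     fdr_max = 1e-6)
  expect_false(cl2$significant)
  # delta-SI gate alone fails the call
  cl3 <- call_events(ev, j, empty_evidence(), "ctl", "trt", dsi_min = 0.25)
  expect_false(cl3$significant)

  # undefined SI excludes the event from the pool entirely
  j4 <- mk(2, 3, 30, 70)
  cl4 <- call_events(detect_alt_ss(j4, idx, "5SS", control = "ctl"),
                     j4, empty_evidence(), "ctl", "trt")
  expect_true(is.na(cl4$si_control))
  expect_true(is.na(cl4$q_value))
  expect_false(cl4$significant)

  # a missing control sample is a configuration error
  expect_error(call_events(ev, j[j$sample_id == "trt", ], empty_evidence(),
                           "ctl", "trt"), "control")
})

test_that("swapping conditions negates delta-SI and preserves p", {
  idx <- plain_index()
  set.seed(3)
  for (i in 1:20) {
    cnt <- as.integer(rpois(4, 40) + 5)
    j <- rbind(mk_junctions("chr1", c(200, 250), c(400, 400),
                            sample_id = "x", count = cnt[1:2]),
               mk_junctions("chr1", c(200, 250), c(400, 400),
                            sample_id = "y", count = cnt[3:4]))
    ev <- detect_alt_ss(j, idx, "5SS", control = "x")
    fwd <- call_events(ev, j, empty_evidence(), "x", "y")
    rev <- call_events(ev, j, empty_evidence(), "y", "x")
    expect_equal(fwd$delta_si, -rev$delta_si)
    expect_equal(fwd$p_value, rev$p_value)
    expect_true(all(na.omit(c(fwd$si_control, fwd$si_treated)) >= 0 &
                    na.omit(c(fwd$si_control, fwd$si_treated)) <= 1))
  }
})
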