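test_that("ratio series divides elementwise and canonicalizes orientation", {
  ds <- tiny_ds(n_sub = 2, n_time = 1, m = 2, stage_map = "A",
                f = function(s, t, i) if (i == 1) c(2, 4)[s] else c(1, 2)[s])
  rs <- ratio_series(ds, "g1", "g2")
  expect_equal(rs$value, c(2, 2))
  expect_false(attr(rs, "flipped"))

  flipped <- ratio_series(ds, "g2", "g1")
  expect_true(attr(flipped, "flipped"))
  expect_equal(flipped$value, rs$value) # canonical i < j either way
  expect_error(ratio_series(ds, "g1", "g1"), "distinct")
})

test_that("the canonical pair count is choose(m, 2)", {
  expect_equal(nrow(feature_pairs(sprintf("f%d", 1:38))), 703)
  expect_equal(nrow(feature_pairs(c("a", "b"))), 1)
})

test_that("effective range is mean +/- 2*p*gamma*sd with population sd", {
  # values with mean 2 and population sd 0.5
  r <- effective_range(c(1.5, 2.5), p = 0.5, gamma = 1.732)
  expect_equal(r$mean, 2)
  expect_equal(r$sd, 0.5)
  expect_equal(c(r$floor, r$ceiling), c(1.134, 2.866))

  # half-width is linear in p
  r25 <- effective_range(c(1.5, 2.5), p = 0.25, gamma = 1.732)
  expect_equal(r25$ceiling - r25$mean, 0.433)

  # n-1 divisor on request
  r_n1 <- effective_range(c(1.5, 2.5), p = 0.5, sd_divisor = "n-1")
  expect_equal(r_n1$sd, sd(c(1.5, 2.5)))

  deg <- effective_range(c(1, 1, 1, 1), p = 0.5)
  expect_true(deg$degenerate)
  expect_equal(c(deg$floor, deg$ceiling), c(1, 1))

  expect_error(effective_range(1, p = 0.5), "insufficient-data")
  expect_error(effective_range(c(1, 2), p = 0), "p must")
})

test_that("sample probability is n_t / (n_t + n_t1)", {
  expect_equal(sample_probability(7, 7), 0.5)
  expect_equal(sample_probability(6, 2), 0.75)
  expect_equal(sample_probability(1, 3), 0.25)
  expect_error(sample_probability(0, 3), "insufficient-data")
})

test_that("range changes classify into the three cases plus identity", {
  expect_equal(classify_change(fake_range(0, 2), fake_range(1, 3)), "upshift")
  expect_equal(classify_change(fake_range(1, 3), fake_range(0, 2)),
               "downshift")
  expect_equal(classify_change(fake_range(0, 4), fake_range(1, 2)), "nested")
  expect_equal(classify_change(fake_range(1, 2), fake_range(0, 4)), "nested")
  # inclusive: shared endpoint still nests
  expect_equal(classify_change(fake_range(0, 2), fake_range(0, 3)), "nested")
  expect_equal(classify_change(fake_range(0, 2), fake_range(0, 2)),
               "identical")
})

test_that("NOR matches the hand oracles and signs the direction", {
  expect_equal(nor_value(fake_range(0, 2), fake_range(3, 5))$value, 1)
  expect_equal(nor_value(fake_range(0, 2), fake_range(1, 3))$value, 0.5)
  expect_equal(nor_value(fake_range(1, 3), fake_range(0, 2))$value, -0.5)
  # nested/identical: no number, case label preserved
  nested <- nor_value(fake_range(0, 4), fake_range(1, 2))
  expect_true(is.na(nested$value))
  expect_equal(nested$case, "nested")
})

test_that("degenerate point ranges follow the documented convention", {
  expect_equal(nor_value(fake_range(1, 1), fake_range(2, 2))$value, 1)
  expect_equal(nor_value(fake_range(2, 2), fake_range(1, 1))$value, -1)
  expect_equal(classify_change(fake_range(1, 1), fake_range(1, 1)),
               "identical")
  expect_equal(classify_change(fake_range(1, 1), fake_range(0, 2)), "nested")
})

test_that("|NOR| equals the unit-segment counting oracle on random intervals", {
  withr::with_seed(42, {
    for (rep in 1:300) {
      e <- sort(sample(0:100, 4, replace = TRUE))
      # random pairing of the four endpoints into two intervals
      pick <- sample(c(TRUE, FALSE, FALSE, TRUE))
      a <- range(e[pick]); b <- range(e[!pick])
      v <- nor_value(fake_range(a[1], a[2]), fake_range(b[1], b[2]))
      if (!is.na(v$value)) {
        expect_equal(abs(v$value),
                     nor_mag_oracle_int(a[1], a[2], b[1], b[2]),
                     tolerance = 1e-10)
        # +/-1 iff disjoint
        expect_equal(abs(v$value) == 1, min(a[2], b[2]) <= max(a[1], b[1]))
      }
    }
  })
})

test_that("NOR is antisymmetric under time reversal", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      a <- fake_range(runif(1, 0, 5), runif(1, 5, 10))
      shift <- runif(1, -6, 6)
      bf <- a$floor + shift + runif(1, -1, 1)
      bc <- a$ceiling + shift + runif(1, -1, 1)
      if (bf > bc) next
      b <- fake_range(bf, bc)
      f <- nor_value(a, b)
      r <- nor_value(b, a)
      if (!is.na(f$value)) expect_equal(r$value, -f$value)
    }
  })
})

test_that("NOR is invariant to rescaling one feature", {
  ds <- tiny_ds(n_sub = 5, n_time = 4, m = 4,
                f = function(s, t, i) exp(0.3 * i + 0.5 * t * (i == 2) +
                                            0.05 * s))
  base <- ratio_audit(ds)
  scaled <- ds
  scaled$data$g2 <- scaled$data$g2 * 137.5
  expect_equal(ratio_audit(scaled)$nor, base$nor, tolerance = 1e-12)
  expect_equal(ratio_audit(scaled)$case, base$case)
})

test_that("audit table covers every pair and transition with p_t", {
  ds <- tiny_ds(n_sub = 3, n_time = 3, m = 3)
  aud <- ratio_audit(ds)
  expect_equal(nrow(aud), choose(3, 2) * 2)
  expect_true(all(aud$p_t == 0.5))
  expect_true(all(aud$floor_t <= aud$ceiling_t))
  expect_true(all(is.na(aud$nor) | abs(aud$nor) <= 1))
})
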