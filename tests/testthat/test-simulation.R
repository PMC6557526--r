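test_that("a transport-dead transporter pool absorbs no iron", {
  for (p in list(switch_params(DMT1_E = 0), swing_params(DMT1_E = 0))) {
    tr <- run_protocol(p, geom, prot2, points_per_challenge = 31L)
    expect_true(all(tr$FeIN_uM == 0))
    expect_true(all(abs(tr$FeOUT_uM - 20) < 1e-12))
  }
})

test_that("trajectories conserve transporter and iron mass", {
  for (p in list(switch_params(), swing_params())) {
    tr <- run_protocol(p, geom, prot2)
    psum <- rowSums(tr[, paste0("P", 1:6)])
    expect_lt(max(abs(psum - 1)), 1e-8)
    for (ch in 1:2) {
      sub <- tr[tr$challenge == ch, ]
      invariant <- geom$V_a * sub$FeOUT_uM + geom$V_cb * sub$FeIN_uM
      expect_lt(max(abs(invariant - invariant[1])), 1e-6)
    }
    expect_true(all(diff(tr$time_min[tr$challenge == 1]) > 0))
  }
})

test_that("finite differences of the trajectory agree with the RHS", {
  # centred differences on a tight trajectory vs the model equations
  for (kind in c("switch", "swing")) {
    p <- if (kind == "switch") switch_params() else swing_params()
    st0 <- if (kind == "switch") switch_initial_state()
           else swing_initial_state()
    tr <- integrate_challenge(p, geom, st0, duration = 15,
                              output_times = seq(0, 15, by = 0.005),
                              rtol = 1e-10, atol = 1e-12)
    idx <- seq(200, nrow(tr) - 200, by = 250)
    for (i in idx) {
      h <- tr$time_rel[i + 1] - tr$time_rel[i - 1]
      fd_fein <- (tr$FeIN_uM[i + 1] - tr$FeIN_uM[i - 1]) / h
      fd_p <- (as.numeric(tr[i + 1, paste0("P", 1:6)]) -
                 as.numeric(tr[i - 1, paste0("P", 1:6)])) / h
      # skip points adjacent to a mode switch (derivative discontinuity)
      if (kind == "switch" &&
          length(unique(tr$mode[(i - 2):(i + 2)])) > 1) next
      st <- model_state(P = as.numeric(tr[i, paste0("P", 1:6)]),
                        FeIN = tr$FeIN_uM[i], FeOUT = tr$FeOUT_uM[i],
                        mode = if (kind == "switch") tr$mode[i]
                               else "endocytic",
                        tol = 1e-6)
      d <- if (kind == "switch") {
        switch_rhs(st, p, geom, tr$mode[i])
      } else {
        swing_rhs(st, p, geom, tr$rho[i])
      }
      expect_equal(fd_fein, d[["dFeIN"]],
                   tolerance = 1e-3 * max(1, abs(d[["dFeIN"]])))
      scale <- max(abs(d[paste0("dP", 1:6)]), 1e-6)
      expect_lt(max(abs(fd_p - d[paste0("dP", 1:6)])) / scale, 1e-3)
    }
  }
})

test_that("switch trajectories alternate modes with monotone P5 episodes", {
  tr <- run_protocol(switch_params(), geom, prot2)
  for (ch in 1:2) {
    sub <- tr[tr$challenge == ch, ]
    runs <- rle(sub$mode)
    expect_gt(length(runs$values), 1)                # at least one switch
    expect_identical(runs$values[1], "endocytic")    # re-init endocytic
    ends <- cumsum(runs$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    for (k in seq_along(runs$values)) {
      p5 <- sub$P5[starts[k]:ends[k]]
      if (runs$values[k] == "endocytic") {
        expect_true(all(diff(p5) >= -1e-9))
      } else {
        expect_true(all(diff(p5) <= 1e-9))
      }
    }
  }
})

test_that("swing endocytosis and exocytosis co-occur", {
  tr <- run_protocol(swing_params(), geom, prot1)
  p <- swing_params()
  endo <- tr$rho * p$k45 * tr$FeOUT_uM * tr$P4 * tr$P5
  back <- tr$rho * p$k64 * tr$P6 * tr$P4
  expect_gt(sum(endo > 1e-6 & back > 1e-6), 0)
})

test_that("halving solver tolerances leaves the endpoint essentially fixed", {
  for (p in list(switch_params(), swing_params())) {
    a <- run_protocol(p, geom, prot1, rtol = 1e-8, atol = 1e-10)
    b <- run_protocol(p, geom, prot1, rtol = 5e-9, atol = 5e-11)
    fa <- a$FeIN_uM[nrow(a)]
    fb <- b$FeIN_uM[nrow(b)]
    expect_lt(abs(fa - fb) / fa, 1e-3)
  }
})

test_that("protocol composition carries state across the cold wash", {
  p <- swing_params()
  single <- integrate_challenge(p, geom, swing_initial_state(), 15,
                                output_times = seq(0, 15, length.out = 151))
  multi <- run_protocol(p, geom, prot1)
  expect_equal(multi$FeIN_uM[nrow(multi)], single$FeIN_uM[nrow(single)],
               tolerance = 1e-9)

  two <- run_protocol(p, geom, prot2)
  b1 <- two[two$challenge == 1, ]
  b2 <- two[two$challenge == 2, ]
  # apical iron renewed to 20 uM, transporter fractions frozen through wash
  expect_equal(b2$FeOUT_uM[1], 20)
  expect_equal(as.numeric(b2[1, paste0("P", 1:6)]),
               as.numeric(b1[nrow(b1), paste0("P", 1:6)]), tolerance = 1e-10)
  expect_equal(b2$FeIN_uM[1], b1$FeIN_uM[nrow(b1)])
  # rho = 1 throughout challenge 1; rho jumps above 1 at challenge-2 start
  expect_true(all(b1$rho == 1))
  expect_equal(b2$rho[1], 1 - 2.8 * (1 - 1.67), tolerance = 1e-9)
})

test_that("uptake series converts concentration gain to pmol per insert", {
  tr <- run_protocol(swing_params(), geom, prot2)
  u1 <- uptake_series(tr, geom, challenge = 1, times = c(3, 6, 9, 12, 15))
  sub <- tr[tr$challenge == 1, ]
  f15 <- sub$FeIN_uM[which(sub$time_rel == 15)]
  expect_equal(u1$uptake_pmol[5], (f15 - sub$FeIN_uM[1]) * geom$V_cb)
  expect_true(all(diff(u1$uptake_pmol) > 0))
  expect_true(all(u1$membrane_fraction >= 0 & u1$membrane_fraction <= 1))
  # challenge-2 series is baseline-subtracted: starts at zero
  u2 <- uptake_series(tr, geom, challenge = 2, times = c(0, 3))
  expect_equal(u2$uptake_pmol[1], 0)
  expect_error(uptake_series(tr, geom, challenge = 3), "out of range")
})
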