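# Channel builders: counts, hermiticity classes, dependencies and the
# rigid-motion identities.

test_that("channel counts follow the theory structure", {
  expect_length(fix_channels("h2o", "ndpt"), 9L)   # 3 N
  expect_length(fix_channels("h2o", "nvpt"), 9L)
  expect_length(fix_channels("h2o", "mfpt"), 3L)   # field directions only
  expect_length(build_ndpt_channels(fix_scf("h2o2_P")), 12L)
})

test_that("velocity channels require all displacement responses", {
  scf <- fix_scf("h2o")
  nd <- fix_responses("h2o", "ndpt")
  expect_error(build_nvpt_channels(scf, nd[-5]), "displacement responses")
  broken <- nd
  broken[[4]] <- list(d1 = NULL)
  expect_error(build_nvpt_channels(scf, broken), "R\\[2,x\\]")
})

test_that("displacement channels are real-symmetric, velocity and field
           channels imaginary-antisymmetric in their stored factors", {
  for (ch in fix_channels("h2o", "ndpt")) {
    expect_symmetric(ch$h, 1e-9)
    expect_symmetric(ch$s, 1e-12)
  }
  for (ch in fix_channels("h2o", "nvpt")) expect_antisymmetric(ch$s, 1e-12)
  for (ch in fix_channels("h2o", "mfpt")) {
    expect_antisymmetric(ch$h, 1e-9)
    expect_antisymmetric(ch$s, 1e-12)
  }
})

test_that("a rigid boost is annihilated: channel sums of the velocity
           perturbation vanish and the summed response is zero", {
  scf <- fix_scf("h2o")
  ch <- fix_channels("h2o", "nvpt")
  rs <- fix_responses("h2o", "nvpt")
  for (beta in 1:3) {
    idx <- seq(beta, 9, by = 3)
    hsum <- Reduce(`+`, lapply(ch[idx], `[[`, "h"))
    ssum <- Reduce(`+`, lapply(ch[idx], `[[`, "s"))
    dsum <- Reduce(`+`, lapply(rs[idx], `[[`, "d1"))
    expect_lt(max(abs(hsum)), 1e-10)
    expect_lt(max(abs(ssum)), 1e-12)
    expect_lt(max(abs(dsum)), 1e-10)
  }
})

test_that("magnetic-field first-order matrices are independent of the
           magnetic gauge origin", {
  ch0 <- fix_channels("h2o", "mfpt")
  scf2 <- fix_scf("h2o", o_mag = c(10, 0, 0))
  ch2 <- build_mfpt_channels(scf2)
  for (a in 1:3) {
    expect_lt(max(abs(ch0[[a]]$s - ch2[[a]]$s)), 1e-12)
    expect_lt(max(abs(ch0[[a]]$h - ch2[[a]]$h)), 1e-10)
  }
})

test_that("uncoupled-imaginary mode drops the exchange response but keeps
           the right-hand side", {
  scf <- fix_scf("h2o")
  nd <- fix_responses("h2o", "ndpt")
  chc <- build_nvpt_channels(scf, nd)
  chu <- build_nvpt_channels(scf, nd, uncoupled = TRUE)
  expect_equal(chc[[1]]$h, chu[[1]]$h)
  expect_false(chu[[1]]$coupling)
  rc <- solve_response(chc[[3]], scf)
  ru <- solve_response(chu[[3]], scf)
  # the exchange response shifts the solution measurably
  expect_gt(max(abs(rc$d1 - ru$d1)), 1e-3)
})
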