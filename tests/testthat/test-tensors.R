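# Polar and axial tensors: sum rules, finite-difference oracles, gauge
# covariance and the free-atom limit.

test_that("length-form polar tensors obey the translational sum rule and
           match finite-difference dipole derivatives", {
  scf <- fix_scf("h2o")
  apt <- apt_length(scf, fix_responses("h2o", "ndpt"))
  expect_lt(max(abs(apply(apt$total, c(2, 3), sum))), 1e-8)
  fd <- fd_apt(fix_mol("h2o"), fix_bset())
  expect_lt(max(abs(apt$total - fd)), 1e-6)
})

test_that("velocity-form polar tensors obey the boost sum rule and agree
           between solvers", {
  scf <- fix_scf("h2o")
  apt_ao <- apt_velocity(scf, fix_responses("h2o", "nvpt", "ao"))
  apt_mo <- apt_velocity(scf, fix_responses("h2o", "nvpt", "mo"))
  expect_lt(max(abs(apply(apt_ao$total, c(2, 3), sum))), 1e-6)
  expect_lt(max(abs(apt_ao$total - apt_mo$total)), 1e-8)
})

test_that("a single neutral atom has vanishing total polar and axial
           tensors in both routes", {
  bs <- read_basis(text = c("He S", " 6.0 1.0", "He S", " 1.2 1.0",
                            "He S", " 0.3 1.0", "He P", " 1.5 1.0",
                            "He P", " 0.4 1.0"))
  mol <- molecule("He", matrix(c(1, 2, 3), 1, 3), unit = "bohr")
  scf <- run_scf(mol, build_ao_basis(mol, bs))
  ndpt <- solve_channel_set(scf, build_ndpt_channels(scf), "ao")
  nv <- solve_channel_set(scf, build_nvpt_channels(scf, ndpt), "ao")
  mf <- solve_channel_set(scf, build_mfpt_channels(scf), "ao")
  al <- apt_length(scf, ndpt); av <- apt_velocity(scf, nv)
  expect_lt(max(abs(al$total)), 1e-10)
  expect_lt(max(abs(av$total)), 1e-10)
  expect_equal(al$elec[1, , ], -mol$n_electrons * diag(3), tolerance = 1e-9)
  anv <- aat_nvpt(scf, nv); amf <- aat_mfpt(scf, mf, ndpt)
  # electronic part cancels the (nonzero) nuclear part exactly: the
  # electron cloud co-moves rigidly with its nucleus
  expect_gt(max(abs(anv$nuc)), 1e-3)
  expect_lt(max(abs(anv$total)), 1e-10)
  expect_lt(max(abs(amf$total)), 1e-10)
})

test_that("axial tensors from both routes agree between AO and MO
           solvers", {
  scf <- fix_scf("h2o2_P")
  nd_ao <- fix_responses("h2o2_P", "ndpt", "ao")
  nd_mo <- fix_responses("h2o2_P", "ndpt", "mo")
  nv_ao <- fix_responses("h2o2_P", "nvpt", "ao")
  nv_mo <- fix_responses("h2o2_P", "nvpt", "mo")
  mf_ao <- fix_responses("h2o2_P", "mfpt", "ao")
  mf_mo <- fix_responses("h2o2_P", "mfpt", "mo")
  expect_lt(max(abs(aat_nvpt(scf, nv_ao)$total -
                    aat_nvpt(scf, nv_mo)$total)), 1e-8)
  expect_lt(max(abs(aat_mfpt(scf, mf_ao, nd_ao)$total -
                    aat_mfpt(scf, mf_mo, nd_mo)$total)), 1e-8)
})

test_that("axial tensors transform under magnetic-origin shifts with the
           exact polar-tensor covariance law", {
  d <- c(10, 0, 0)
  scf0 <- fix_scf("h2o"); scf1 <- fix_scf("h2o", o_mag = d)
  nv0 <- fix_responses("h2o", "nvpt"); nd0 <- fix_responses("h2o", "ndpt")
  nv1 <- fix_responses("h2o", "nvpt", o_mag = d)
  nd1 <- fix_responses("h2o", "ndpt", o_mag = d)
  mf0 <- fix_responses("h2o", "mfpt"); mf1 <- fix_responses("h2o", "mfpt", o_mag = d)
  law <- function(P) {
    out <- array(0, dim(P))
    cc <- 4 * phys_constants$c_au
    for (l in seq_len(dim(P)[1])) for (a in 1:3) for (b in 1:3) {
      acc <- 0
      for (g in 1:3) for (dl in 1:3)
        acc <- acc + vcdpt:::.eps3[a, g, dl] * d[g] * P[l, dl, b]
      out[l, a, b] <- -acc / cc
    }
    out
  }
  dv <- aat_nvpt(scf1, nv1)$total - aat_nvpt(scf0, nv0)$total
  expect_lt(max(abs(dv - law(apt_velocity(scf0, nv0)$total))), 1e-10)
  db <- aat_mfpt(scf1, mf1, nd1)$total - aat_mfpt(scf0, mf0, nd0)$total
  expect_lt(max(abs(db - law(apt_length(scf0, nd0)$total))), 1e-10)
})

test_that("strength tables are computed per vibrational mode with
           nonnegative dipole strengths", {
  tab <- fix_strengths("h2o", "nvpt")
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$D_au >= 0))
  expect_true(all(is.finite(tab$R_au)))
  expect_equal(tab$D_1e40esu2cm2 / tab$D_au,
               rep(phys_constants$dipole_strength_au_to_1e40esu2cm2, 3))
})

test_that("strengths refuse mismatched atom counts", {
  apt <- apt_length(fix_scf("h2o"), fix_responses("h2o", "ndpt"))
  vib2 <- fix_vib("h2")
  expect_error(strengths(apt, NULL, vib2), "mismatch")
})

test_that("rotational strengths from the magnetic-field route approach the
           velocity route at the polarized basis level", {
  # geometry and normal modes fixed (minimal-basis harmonic analysis) so
  # the comparison isolates the tensors themselves
  mol <- fix_mol("h2o2_P")
  vib <- fix_vib("h2o2_P")
  basis <- build_ao_basis(mol, builtin_basis("6-31gss"))
  scf <- run_scf(mol, basis)
  nd <- solve_channel_set(scf, build_ndpt_channels(scf), "ao")
  nv <- solve_channel_set(scf, build_nvpt_channels(scf, nd), "ao")
  mf <- solve_channel_set(scf, build_mfpt_channels(scf), "ao")
  sv <- strengths(apt_velocity(scf, nv), aat_nvpt(scf, nv), vib)
  sb <- strengths(apt_length(scf, nd), aat_mfpt(scf, mf, nd), vib)
  k <- which.max(abs(sv$R_au))
  expect_equal(sb$R_au[k], sv$R_au[k], tolerance = 0.2)
})
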