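test_that("parameter container enforces the exponent domain and model limits", {
  expect_error(relaxation_parameters("debye", delta_eps = 0.2, tau = -1),
               "tau")
  expect_error(relaxation_parameters("cole_cole", delta_eps = 0.2, tau = 0.2,
                                     sigma_cc = 1.2), "\\(0, 1\\]")
  p <- relaxation_parameters("cole_cole", delta_eps = 0.2, tau = 0.2,
                             sigma_cc = 0.8, sigma_cd = 0.5)
  expect_identical(p$sigma_cd, 1)   # tag forces the Cole-Cole limit
})

test_that("model evaluation hits the static and Debye-peak identities", {
  p <- relaxation_parameters("debye", delta_eps = 0.4, tau = 0.3, eps_inf = 2)
  at0 <- evaluate_model(p, 1e-12)
  expect_equal(at0$eps_r, 2.4, tolerance = 1e-9)   # eps_s at omega -> 0
  expect_equal(at0$eps_i, 0, tolerance = 1e-9)
  # at omega tau = 1: eps_r = eps_inf + de/2, eps_i = de/2
  f1 <- 1 / (2 * pi * 0.3)
  at1 <- evaluate_model(p, f1)
  expect_equal(at1$eps_r, 2.2, tolerance = 1e-12)
  expect_equal(at1$eps_i, 0.2, tolerance = 1e-12)
})

test_that("the family reduces to Debye when both exponents are 1", {
  set.seed(31)
  f <- sort(runif(20, 0.05, 3))
  hn <- relaxation_parameters("havriliak_negami", delta_eps = 0.37, tau = 0.21,
                              eps_inf = 2.2, sigma_cc = 1, sigma_cd = 1)
  got <- evaluate_model(hn, f)
  oracle <- debye_eps_oracle(f, 0.37, 0.21, 2.2)
  expect_equal(got$eps_r, Re(oracle), tolerance = 1e-12)
  expect_equal(got$eps_i, -Im(oracle), tolerance = 1e-12)
})

test_that("Cole-Davidson evaluation matches independent complex arithmetic", {
  # parameters characteristic of Baltic amber loss spectra
  p <- relaxation_parameters("cole_davidson", delta_eps = 0.215, tau = 0.202,
                             eps_inf = 2.4, sigma_cd = 0.444)
  got <- evaluate_model(p, 1)
  w <- 2 * pi * 1 * 0.202
  z <- 1 + 1i * w             # (1 + i omega tau)
  val <- 2.4 + 0.215 * exp(-0.444 * (log(Mod(z)) + 1i * Arg(z)))
  expect_equal(got$eps_r, Re(val), tolerance = 1e-12)
  expect_equal(got$eps_i, -Im(val), tolerance = 1e-12)
})

test_that("static and high-frequency limits hold for random parameter draws", {
  # the HN family approaches its limits as (omega tau)^(+/- exponent), so
  # the achievable closeness at a finite frequency depends on the
  # exponents; the checks use the leading asymptotic term as the bound
  set.seed(33)
  for (i in 1:10) {
    p <- relaxation_parameters("havriliak_negami",
                               delta_eps = runif(1, 0.05, 1),
                               tau = runif(1, 0.05, 1),
                               eps_inf = runif(1, 1, 3),
                               sigma_cc = runif(1, 0.3, 1),
                               sigma_cd = runif(1, 0.3, 1))
    lo <- evaluate_model(p, 1e-6)
    hi <- evaluate_model(p, 1e6)
    wt_lo <- 2 * pi * 1e-6 * p$tau
    wt_hi <- 2 * pi * 1e6 * p$tau
    bound_lo <- 5 * p$delta_eps * p$sigma_cd * wt_lo^p$sigma_cc + 1e-12
    bound_hi <- 5 * p$delta_eps * wt_hi^(-p$sigma_cc * p$sigma_cd) + 1e-12
    expect_lt(abs(lo$eps_r - (p$eps_inf + p$delta_eps)), bound_lo)
    expect_lt(lo$eps_i, bound_lo)
    expect_lt(abs(hi$eps_r - p$eps_inf), bound_hi)
    expect_lt(hi$eps_i, bound_hi)
  }
  # for the Debye limit the approach is first order in omega tau, and the
  # limits hold to 1e-9 at suitably extreme frequencies
  pd <- relaxation_parameters("debye", delta_eps = 0.5, tau = 0.3, eps_inf = 2)
  lo <- evaluate_model(pd, 1e-12)
  hi <- evaluate_model(pd, 1e12)
  expect_lt(abs(lo$eps_r - 2.5) + lo$eps_i, 1e-9)
  expect_lt(abs(hi$eps_r - 2) + hi$eps_i, 1e-9)
})

test_that("Debye loss peaks at f = 1/(2 pi tau) with height delta_eps/2", {
  set.seed(34)
  for (i in 1:5) {
    de <- runif(1, 0.1, 1); tau <- runif(1, 0.1, 0.5)
    p <- relaxation_parameters("debye", delta_eps = de, tau = tau)
    f <- seq(0.01, 5, length.out = 4000)
    sp <- evaluate_model(p, f)
    fpk <- f[which.max(sp$eps_i)]
    expect_equal(fpk, 1 / (2 * pi * tau), tolerance = 2 * (f[2] - f[1]))
    expect_equal(max(sp$eps_i), de / 2, tolerance = 1e-4)
  }
})

test_that("noiseless self-fits are exact and deterministic", {
  f <- seq(0.15, 2, length.out = 120)
  p <- relaxation_parameters("debye", delta_eps = 0.2, tau = 0.3)
  perm <- evaluate_model(p, f)
  perm$band <- band_mask(0.15, 2)
  ft <- fit_imaginary(perm, "debye")
  expect_equal(ft$params$delta_eps, 0.2, tolerance = 1e-6)
  expect_equal(ft$params$tau, 0.3, tolerance = 1e-6)
  expect_equal(ft$r_squared, 1, tolerance = 1e-9)
  expect_true(ft$converged)
  # no random initialization: a repeat run is bit-identical
  ft2 <- fit_imaginary(perm, "debye")
  expect_identical(ft$params$delta_eps, ft2$params$delta_eps)
  expect_identical(ft$residuals, ft2$residuals)
  expect_error(fit_imaginary(evaluate_model(p, f[1:5]), "debye"), "8 in-band")
})

test_that("nested models never beat richer ones in R-squared", {
  for (seed in c(41, 42, 43)) {
    perm <- cc_noisy_perm(seed)
    r2 <- vapply(c("debye", "cole_cole", "havriliak_negami"),
                 function(m) fit_imaginary(perm, m)$r_squared, 1)
    expect_gte(r2[["cole_cole"]], r2[["debye"]] - 1e-9)
    expect_gte(r2[["havriliak_negami"]], r2[["cole_cole"]] - 1e-9)
  }
})

test_that("a misspecified Debye fit scores below the generating Cole-Davidson model", {
  f <- seq(0.15, 2, length.out = 150)
  p <- relaxation_parameters("cole_davidson", delta_eps = 0.2, tau = 0.2,
                             sigma_cd = 0.5)
  truth <- evaluate_model(p, f)
  set.seed(51)
  y <- truth$eps_i * (1 + 0.01 * rnorm(150))
  perm <- permittivity_spectrum(f, truth$eps_r, y, band_mask(0.15, 2))
  ftd <- fit_imaginary(perm, "debye")
  ftcd <- fit_imaginary(perm, "cole_davidson")
  expect_lt(ftd$r_squared, ftcd$r_squared)
})

test_that("model ranking is lexicographic with deterministic tie-breaks", {
  perm <- cc_noisy_perm(61)
  fits <- lapply(c("debye", "cole_cole", "cole_davidson"),
                 function(m) fit_imaginary(perm, m))
  tab <- compare_models(fits)
  expect_identical(tab$model[1], "cole_cole")
  expect_identical(tab$model[nrow(tab)], "debye")
  expect_identical(tab$rank, seq_len(3L))
  # single fit is trivially first
  expect_identical(compare_models(fits[2])$rank, 1L)
  # identical duplicated fits tie, broken by model-tag order (here equal
  # tags: order must still be deterministic across calls)
  t1 <- compare_models(list(fits[[2]], fits[[2]]))
  t2 <- compare_models(list(fits[[2]], fits[[2]]))
  expect_identical(t1, t2)
  # differing grids are not comparable
  other <- cc_noisy_perm(61, n = 120L)
  expect_error(compare_models(list(fits[[1]], fit_imaginary(other, "debye"))),
               "frequency grid")
})

test_that("runs test matches exact enumeration and flags extremes", {
  # +++--- : runs = 2; exact p by enumeration over all C(6,3) orderings
  r <- residual_randomness(c(1, 1, 1, -1, -1, -1, 0, 0, 0, 0)[1:10])
  perms <- combn(6, 3)
  runs_of <- function(pos) {
    s <- rep(-1, 6); s[pos] <- 1
    1 + sum(diff(s) != 0)
  }
  all_runs <- apply(perms, 2, runs_of)
  p_lo <- mean(all_runs <= 2)
  p_exact <- min(1, 2 * min(p_lo, mean(all_runs >= 2)))
  expect_equal(r$runs, 2L)
  expect_equal(r$p_value, p_exact, tolerance = 1e-12)
  # alternating signs: maximal runs, tiny p
  alt <- rep(c(1, -1), 10)
  ra <- residual_randomness(alt)
  expect_equal(ra$runs, 20L)
  expect_lt(ra$p_value, 0.01)
  # one-signed residuals are degenerate
  rd <- residual_randomness(rep(1, 12))
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 0)
  expect_error(residual_randomness(1:5), "at least 10")
})
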