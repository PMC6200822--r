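# Multilocus HKA neutrality test, one-species polymorphism vs divergence
# to an outgroup, with parameters fitted by direct X2 minimization.

# Model expectations and variances for one locus.
hkaMoments <- function(thetaSite, T, n, Lpoly, Ldiv) {
  a1 <- harmonicA1(n)
  a2 <- harmonicA2(n)
  cS <- thetaSite * Lpoly
  cD <- thetaSite * Ldiv
  coefD <- (n + 1) / (2 * n)
  ES <- cS * a1
  VS <- ES + cS^2 * a2
  ED <- cD * (T + coefD)
  VD <- ED + (cD * coefD)^2
  list(ES = ES, VS = VS, ED = ED, VD = VD)
}

hkaX2 <- function(thetaSite, T, S, D, n, Lpoly, Ldiv) {
  x2 <- 0
  for (i in seq_along(S)) {
    mom <- hkaMoments(thetaSite[i], T, n[i], Lpoly[i], Ldiv[i])
    x2 <- x2 + (S[i] - mom$ES)^2 / mom$VS + (D[i] - mom$ED)^2 / mom$VD
  }
  x2
}

#' Multilocus Hudson-Kreitman-Aguade (HKA) neutrality test
#'
#' Compares within-species polymorphism (segregating sites S_i) with
#' divergence to an outgroup (mean difference count D_i) across L >= 2
#' loci. Under neutrality both are proportional to the same per-locus
#' mutation parameter theta_i, so a common scaled divergence time T and
#' the theta_i can be fitted jointly; departures inflate the
#' goodness-of-fit statistic. Expectations follow the 1987 model:
#' `E[S_i] = theta_i a1(n_i) L_poly`, `Var[S_i] = E[S_i] +
#' (theta_i L_poly)^2 a2(n_i)`, `E[D_i] = theta_i L_div (T +
#' (n_i+1)/(2 n_i))`, `Var[D_i] = E[D_i] + (theta_i L_div
#' (n_i+1)/(2 n_i))^2`, with theta_i per site. Parameters minimize
#' `X2 = sum (S_i - E S_i)^2 / Var S_i + (D_i - E D_i)^2 / Var D_i`
#' numerically (L-BFGS-B on log parameters, moment-based start); p comes
#' from the chi-square with `2L - (L + 1) = L - 1` degrees of freedom.
#'
#' @param loci data.frame with one row per locus and columns `locus`
#'   (optional id), `S` (segregating sites), `n` (sample size), `D`
#'   (mean pairwise divergence count to the outgroup), `L_poly` and
#'   `L_div` (sites surveyed for polymorphism / divergence).
#' @return An [HKAResult-class] object.
#' @examples
#' tab <- data.frame(S = c(10, 2), n = c(10, 10), D = c(20, 22),
#'                   L_poly = c(500, 500), L_div = c(500, 500))
#' hkaTest(tab)
#' @export
hkaTest <- function(loci) {
  L <- nrow(loci)
  if (L < 2L) stop("HKA requires at least 2 loci (df = L - 1 would be 0)")
  S <- as.numeric(loci$S)
  D <- as.numeric(loci$D)
  n <- as.numeric(loci$n)
  Lp <- as.numeric(loci$L_poly)
  Ld <- as.numeric(loci$L_div)
  if (any(n < 2)) stop("each locus needs a sample size n >= 2")
  ids <- if (!is.null(loci$locus)) as.character(loci$locus) else
    paste0("locus", seq_len(L))

  # Moment starts: theta from Watterson, T from the divergence excess.
  a1 <- vapply(n, harmonicA1, numeric(1))
  theta0 <- pmax(S / (a1 * Lp), 1e-6)
  coefD <- (n + 1) / (2 * n)
  T0 <- max(mean(D / (theta0 * Ld) - coefD), 0.1)

  obj <- function(par) {
    th <- exp(par[seq_len(L)])
    T <- exp(par[L + 1L])
    hkaX2(th, T, S, D, n, Lp, Ld)
  }
  fit <- stats::optim(c(log(theta0), log(T0)), obj, method = "L-BFGS-B",
                      control = list(maxit = 2000, factr = 1e4))
  # Polish from a second start to guard against local minima.
  fit2 <- stats::optim(c(log(theta0 * 2), log(T0 + 1)), obj,
                       method = "L-BFGS-B",
                       control = list(maxit = 2000, factr = 1e4))
  if (fit2$value < fit$value) fit <- fit2
  if (!fit$convergence %in% c(0L, 52L) && fit$value > 1e-8)
    stop("HKA optimizer failed to converge (code ", fit$convergence,
         "): ", fit$message)
  th <- exp(fit$par[seq_len(L)])
  T <- exp(fit$par[L + 1L])
  X2 <- fit$value
  df <- L - 1L
  tab <- do.call(rbind, lapply(seq_len(L), function(i) {
    mom <- hkaMoments(th[i], T, n[i], Lp[i], Ld[i])
    data.frame(locus = ids[i], n = n[i], S_obs = S[i], S_exp = mom$ES,
               S_var = mom$VS, D_obs = D[i], D_exp = mom$ED,
               D_var = mom$VD, stringsAsFactors = FALSE)
  }))
  methods::new("HKAResult", table = tab, thetaSite = th,
               thetaLocus = th * Lp, T = T, X2 = X2, df = df,
               pValue = stats::pchisq(X2, df, lower.tail = FALSE),
               convergence = as.integer(fit$convergence))
}
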