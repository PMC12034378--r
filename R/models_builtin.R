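# Built-in example systems: generalized Lotka-Volterra, repressilator
# (Hill-form and mass-action expansion), and fluorescent-protein maturation.

#' Generalized Lotka-Volterra model with 16 species
#'
#' A ring-coupled competitive system:
#' `dx_n/dt = x_n (r_n - k_n x_{n+1})` for `n = 1..15` and
#' `dx_16/dt = x_16 (r_16 - k_16 x_1)`, with birth rates `r_n = n/80` fixed.
#' The interaction rates `k_n` are the free parameters; they are tied so that
#' only `m` distinct values remain (`k_{n1} = k_{n2}` whenever
#' `n1 = n2 (mod m)`), which lets the number of free parameters be varied
#' within a fixed model structure.
#'
#' @param m number of distinct interaction parameters; must divide 16.
#' @param x0 initial condition (default all states at 1).
#' @return An [ode_model] with `K = 16` states and `P = m` free parameters.
#' @export
make_lotka_volterra <- function(m = 4, x0 = rep(1, 16)) {
  K <- 16
  if (!(m %in% c(1, 2, 4, 8, 16))) {
    stop("'m' must divide 16 (one of 1, 2, 4, 8, 16)")
  }
  r <- seq_len(K) / 80
  nxt <- c(seq_len(K - 1) + 1, 1)           # prey/partner index of each state
  pidx <- ((seq_len(K) - 1) %% m) + 1       # tied parameter of each state
  g <- function(x, t) {
    G <- matrix(0, K, m)
    G[cbind(seq_len(K), pidx)] <- -x * x[nxt]
    G
  }
  h <- function(x, t) r * x
  jac <- function(x, beta, t) {
    k <- beta[pidx]
    J <- matrix(0, K, K)
    diag(J) <- r - k * x[nxt]
    J[cbind(seq_len(K), nxt)] <- -k * x
    J
  }
  ode_model(g = g, h = h, jac = jac, x0 = x0,
            state_names = paste0("x", seq_len(K)),
            param_names = paste0("k", seq_len(m)),
            fixed_params = stats::setNames(r, paste0("r", seq_len(K))),
            name = sprintf("lotka_volterra_m%d", m))
}

#' Repressilator model (Hill form or mass-action expansion)
#'
#' Three transcriptional repressors in a ring, each repressing the next. The
#' Hill form has six states (mRNAs `m1..m3`, proteins `p1..p3`):
#' `dm_n/dt = 0.0005 + 0.5 alpha_n / (alpha_n + 0.00025 p_rep(n)^2) - 0.3466 m_n`,
#' `dp_n/dt = 20 m_n - beta_n p_n`, with repressor pairing
#' (n, rep) = (1,3), (2,1), (3,2). The Hill term is nonlinear in `alpha_n`, so
#' the Hill form can be simulated and fit by trajectory matching but not by
#' gradient matching.
#'
#' With `expanded = TRUE`, the quasi-steady-state approximation behind the
#' Hill term is undone by reintroducing one promoter-occupancy state `c_n` per
#' gene (fraction of promoter bound by repressor):
#' `dc_n/dt = kappa * (0.00025 p_rep(n)^2 (1 - c_n) - alpha_n c_n)` and
#' `dm_n/dt = 0.0005 + 0.5 (1 - c_n) - 0.3466 m_n`. Setting `dc_n/dt = 0`
#' recovers the Hill form exactly, and the expansion is linear in the six free
#' parameters `(alpha_1..3, beta_1..3)`, making it amenable to gradient
#' matching with the `c_n` treated as hidden states.
#'
#' @param expanded if `TRUE`, return the 9-state mass-action expansion.
#' @param kappa time-scale separation constant of the promoter binding
#'   kinetics (1/min); larger values push the expansion toward its
#'   quasi-steady-state (Hill) limit.
#' @param x0_mrna,x0_protein initial mRNA and protein concentrations (uM).
#'   The defaults are a (rounded) point on the limit cycle of the system with
#'   nominal parameters (`alpha = 0.16`, `beta = 0.0693`), so simulated cells
#'   start mid-oscillation with the three repressors out of phase, rather
#'   than going through an induction transient much faster than typical
#'   sampling intervals.
#' @param alpha0 nominal promoter-affinity value (uM) used only to set the
#'   known initial occupancy `c_n(0)` at its quasi-steady-state value.
#' @return An [ode_model]; 6 states for the Hill form, 9 for the expansion.
#' @export
make_repressilator <- function(expanded = TRUE, kappa = 10,
                               x0_mrna = c(0.040, 0.502, 0.244),
                               x0_protein = c(30.2, 71.6, 141.6),
                               alpha0 = 0.16) {
  rep_of <- c(3, 1, 2)  # protein repressing gene n
  pnames <- c(paste0("alpha", 1:3), paste0("beta", 1:3))
  if (!expanded) {
    f <- function(x, beta, t) {
      m <- x[1:3]; p <- x[4:6]
      a <- beta[1:3]; bdeg <- beta[4:6]
      dm <- 0.0005 + 0.5 * a / (a + 0.00025 * p[rep_of]^2) - 0.3466 * m
      dp <- 20 * m - bdeg * p
      c(dm, dp)
    }
    return(ode_model(f = f, x0 = c(x0_mrna, x0_protein),
                     state_names = c(paste0("m", 1:3), paste0("p", 1:3)),
                     param_names = pnames,
                     fixed_params = c(m_leak = 0.0005, m_max = 0.5,
                                      K_bind = 0.00025, m_deg = 0.3466,
                                      k_transl = 20),
                     name = "repressilator_hill"))
  }
  g <- function(x, t) {
    p <- x[4:6]; cc <- x[7:9]
    G <- matrix(0, 9, 6)
    G[cbind(7:9, 1:3)] <- -kappa * cc      # -kappa * alpha_n * c_n
    G[cbind(4:6, 4:6)] <- -p               # -beta_n * p_n
    G
  }
  h <- function(x, t) {
    m <- x[1:3]; p <- x[4:6]; cc <- x[7:9]
    dm <- 0.0005 + 0.5 * (1 - cc) - 0.3466 * m
    dp <- 20 * m
    dc <- kappa * 0.00025 * p[rep_of]^2 * (1 - cc)
    c(dm, dp, dc)
  }
  jac <- function(x, beta, t) {
    p <- x[4:6]; cc <- x[7:9]
    J <- matrix(0, 9, 9)
    J[cbind(1:3, 1:3)] <- -0.3466
    J[cbind(1:3, 7:9)] <- -0.5
    J[cbind(4:6, 1:3)] <- 20
    J[cbind(4:6, 4:6)] <- -beta[4:6]
    J[cbind(7:9, 3 + rep_of)] <- kappa * 0.0005 * p[rep_of] * (1 - cc)
    J[cbind(7:9, 7:9)] <- -kappa * (0.00025 * p[rep_of]^2 + beta[1:3])
    J
  }
  c0 <- 0.00025 * x0_protein[rep_of]^2 /
    (0.00025 * x0_protein[rep_of]^2 + alpha0)
  ode_model(g = g, h = h, jac = jac, x0 = c(x0_mrna, x0_protein, c0),
            state_names = c(paste0("m", 1:3), paste0("p", 1:3),
                            paste0("c", 1:3)),
            param_names = pnames,
            fixed_params = c(m_leak = 0.0005, m_max = 0.5, K_bind = 0.00025,
                             m_deg = 0.3466, k_transl = 20, kappa = kappa),
            name = "repressilator_expanded")
}

#' Fluorescent-protein expression and maturation model
#'
#' Transcription is switched on step-wise at `t = t_on`; mRNA (`M`) is
#' translated into immature dark protein (`D`), which matures into the
#' fluorescent form (`F`) in one or two rate-limiting steps. All species are
#' diluted by growth at rate `k_dil`. One-step kinetics:
#' `dM/dt = k_r 1(t >= t_on) - (k_dr + k_dil) M`,
#' `dD/dt = k_p M - (k_m + k_dil) D`,
#' `dF/dt = k_m D - k_dil F`.
#' The two-step variant inserts a nonfluorescent intermediate `D2` with a
#' shared maturation rate (`k_m := k_m1 = k_m2`, since the two rates cannot be
#' separated from fluorescence data alone):
#' `dD1/dt = k_p M - (k_m + k_dil) D1`, `dD2/dt = k_m D1 - (k_m + k_dil) D2`,
#' `dF/dt = k_m D2 - k_dil F`.
#' The free parameters are `beta = (k_p, k_m)` (protein synthesis and
#' maturation rates, 1/min); `k_r`, `k_dr`, `k_dil` are fixed for structural
#' identifiability.
#'
#' @param steps 1 or 2 rate-limiting maturation steps.
#' @param k_r mRNA synthesis rate after induction (transcripts/min).
#' @param k_dr mRNA degradation rate (1/min).
#' @param k_dil dilution rate due to growth (1/min).
#' @param t_on induction onset time (min); transcription is zero before it.
#' @return An [ode_model] with zero initial conditions.
#' @export
make_fp_maturation <- function(steps = 1, k_r = 0.1, k_dr = 0.07,
                               k_dil = 0.004, t_on = 0) {
  steps <- as.integer(steps)
  if (!(steps %in% c(1L, 2L))) stop("'steps' must be 1 or 2")
  fixed <- c(k_r = k_r, k_dr = k_dr, k_dil = k_dil, t_on = t_on)
  if (steps == 1L) {
    g <- function(x, t) {
      # columns: k_p, k_m ; states: M, D, F
      matrix(c(0, x[1], 0,
               0, -x[2], x[2]), 3, 2)
    }
    h <- function(x, t) {
      c(k_r * as.numeric(t >= t_on) - (k_dr + k_dil) * x[1],
        -k_dil * x[2],
        -k_dil * x[3])
    }
    jac <- function(x, beta, t) {
      matrix(c(-(k_dr + k_dil), beta[1], 0,
               0, -(beta[2] + k_dil), beta[2],
               0, 0, -k_dil), 3, 3)
    }
    return(ode_model(g = g, h = h, jac = jac, x0 = c(0, 0, 0),
                     state_names = c("M", "D", "F"),
                     param_names = c("k_p", "k_m"),
                     fixed_params = fixed, name = "fp_one_step"))
  }
  g <- function(x, t) {
    # states: M, D1, D2, F ; columns: k_p, k_m
    matrix(c(0, x[1], 0, 0,
             0, -x[2], x[2] - x[3], x[3]), 4, 2)
  }
  h <- function(x, t) {
    c(k_r * as.numeric(t >= t_on) - (k_dr + k_dil) * x[1],
      -k_dil * x[2],
      -k_dil * x[3],
      -k_dil * x[4])
  }
  jac <- function(x, beta, t) {
    km <- beta[2]
    matrix(c(-(k_dr + k_dil), beta[1], 0, 0,
             0, -(km + k_dil), km, 0,
             0, 0, -(km + k_dil), km,
             0, 0, 0, -k_dil), 4, 4)
  }
  ode_model(g = g, h = h, jac = jac, x0 = c(0, 0, 0, 0),
            state_names = c("M", "D1", "D2", "F"),
            param_names = c("k_p", "k_m"),
            fixed_params = fixed, name = "fp_two_step")
}
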