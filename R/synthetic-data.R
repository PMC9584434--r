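# Ground-truth benchmark: a six-gene Hill ODE oscillator with unit decay
# and shared Hill exponent n = 5, at three widely separated
# parameterisations, plus a spurious sinusoid gene G.

.gtPairs <- c("B,F", "F,E", "C,B", "E,D", "E,C",
              "A,C", "B,E", "A,D", "D,C", "F,A")

.gtTable <- local({
  # columns: the three stored parameterisations; rows: Gamma, Omega, theta
  # for each regulated pair (source, target)
  m <- matrix(c(
    # col1          col2          col3
    0.1071294686, 0.1247062357, 0.1054951481,  # Gamma_B,F
    1.1980739800, 2.6962820818, 2.0937997708,  # Omega_B,F
    0.0055430383, 0.3637389501, 0.5673228474,  # theta_B,F
    0.0175034071, 0.5011731410, 0.2455250910,  # Gamma_F,E
    0.8244263241, 0.1209518139, 1.5683516101,  # Omega_F,E
    1.3029576011, 1.5201526697, 0.8518129907,  # theta_F,E
    0.0011155796, 0.1958127811, 0.0966678191,  # Gamma_C,B
    1.9491367094, 1.5533875523, 2.3227225179,  # Omega_C,B
    2.9810640658, 3.5689954379, 3.1482725035,  # theta_C,B
    0.2201158863, 0.2141223259, 0.0529032838,  # Gamma_E,D
    3.6625872030, 2.9847903373, 0.5576409019,  # Omega_E,D
    0.5390177462, 1.0533043028, 0.3727988706,  # theta_E,D
    1.6499211746, 0.4358121924, 0.0676798151,  # Gamma_E,C
    0.3900059619, 0.5490600005, 1.7873719546,  # Omega_E,C
    0.0088027178, 1.4982296668, 1.4187706085,  # theta_E,C
    0.1007846993, 0.4132072556, 0.0928646536,  # Gamma_A,C
    0.2578132626, 2.2969011759, 1.2197732691,  # Omega_A,C
    0.2419230934, 0.6819105357, 1.7352137828,  # theta_A,C
    0.0096494654, 0.2810071904, 0.6185173324,  # Gamma_B,E
    0.7130182868, 2.2758756351, 3.7129348824,  # Omega_B,E
    1.5106988697, 0.6517967757, 0.7417231063,  # theta_B,E
    0.0542085170, 0.1210124702, 0.2731054750,  # Gamma_A,D
    0.8946601377, 2.0147888846, 0.5576412929,  # Omega_A,D
    0.6862437739, 1.1760092769, 0.4867821250,  # theta_A,D
    0.0624991995, 1.1124366444, 0.2593204887,  # Gamma_D,C
    1.3297386450, 3.2764296326, 4.0461307096,  # Omega_D,C
    1.0817547392, 2.1191576389, 0.1931413047,  # theta_D,C
    0.1885194202, 0.0567438444, 0.0398781756,  # Gamma_F,A
    1.4488910403, 2.1341889294, 6.1842079625   # Omega_F,A
  ), ncol = 3, byrow = TRUE)
  m <- rbind(m, c(0.7285164419, 0.3815742876, 1.4900313815))  # theta_F,A
  rownames(m) <- as.vector(vapply(.gtPairs, function(p)
    paste0(c("Gamma_", "Omega_", "theta_"), p), character(3)))
  colnames(m) <- paste0("col", 1:3)
  m
})

#' Ground-truth Hill ODE parameters
#'
#' Per regulated pair (source, target): basal term Gamma, regulation
#' amplitude Omega and threshold theta for the stored parameterisation;
#' the Hill exponent is 5 throughout and every variable decays at unit
#' rate.
#'
#' @param column parameterisation 1, 2 or 3.
#' @return named list with elements \code{Gamma}, \code{Omega},
#'   \code{theta} (named by \code{"source,target"} pairs) and
#'   \code{nHill}.
#' @export
groundTruthParams <- function(column) {
  stopifnot(column %in% 1:3)
  v <- .gtTable[, column]
  g <- v[grep("^Gamma_", names(v))]
  o <- v[grep("^Omega_", names(v))]
  th <- v[grep("^theta_", names(v))]
  names(g) <- sub("^Gamma_", "", names(g))
  names(o) <- sub("^Omega_", "", names(o))
  names(th) <- sub("^theta_", "", names(th))
  list(Gamma = g, Omega = o, theta = th, nHill = 5)
}

#' The full stored parameter table
#'
#' @return matrix of the 31 stored parameters (10 regulated pairs x
#'   Gamma/Omega/theta, plus the shared Hill exponent row implicit at 5)
#'   by the three parameterisations.
#' @export
groundTruthParamTable <- function() .gtTable

.hillAct <- function(x, th, n) x^n / (x^n + th^n)
.hillRep <- function(x, th, n) th^n / (x^n + th^n)

# right-hand sides of the six- and five-variable systems
.gtRhs <- function(t, y, p) {
  G <- p$Gamma; O <- p$Omega; th <- p$theta; n <- p$nHill
  A <- y[1]; B <- y[2]; C <- y[3]; D <- y[4]; E <- y[5]; F <- y[6]
  dA <- -A + G[["F,A"]] + O[["F,A"]] * .hillAct(F, th[["F,A"]], n)
  dB <- -B + G[["C,B"]] + O[["C,B"]] * .hillAct(C, th[["C,B"]], n)
  dC <- -C + (G[["A,C"]] + O[["A,C"]] * .hillAct(A, th[["A,C"]], n) +
              G[["E,C"]] + O[["E,C"]] * .hillAct(E, th[["E,C"]], n)) *
             (G[["D,C"]] + O[["D,C"]] * .hillRep(D, th[["D,C"]], n))
  dD <- -D + (G[["A,D"]] + O[["A,D"]] * .hillRep(A, th[["A,D"]], n)) *
             (G[["E,D"]] + O[["E,D"]] * .hillRep(E, th[["E,D"]], n))
  dE <- -E + (G[["B,E"]] + O[["B,E"]] * .hillRep(B, th[["B,E"]], n)) *
             (G[["F,E"]] + O[["F,E"]] * .hillAct(F, th[["F,E"]], n))
  dF <- -F + G[["B,F"]] + O[["B,F"]] * .hillRep(B, th[["B,F"]], n)
  list(c(dA, dB, dC, dD, dE, dF))
}

.gtRhsReduced <- function(t, y, p) {
  G <- p$Gamma; O <- p$Omega; th <- p$theta; n <- p$nHill
  A <- y[1]; B <- y[2]; C <- y[3]; E <- y[4]; F <- y[5]
  dA <- -A + G[["F,A"]] + O[["F,A"]] * .hillAct(F, th[["F,A"]], n)
  dB <- -B + G[["C,B"]] + O[["C,B"]] * .hillAct(C, th[["C,B"]], n)
  dC <- -C + G[["A,C"]] + O[["A,C"]] * .hillAct(A, th[["A,C"]], n) +
             G[["E,C"]] + O[["E,C"]] * .hillAct(E, th[["E,C"]], n)
  dE <- -E + (G[["B,E"]] + O[["B,E"]] * .hillRep(B, th[["B,E"]], n)) *
             (G[["F,E"]] + O[["F,E"]] * .hillAct(F, th[["F,E"]], n))
  dF <- -F + G[["B,F"]] + O[["B,F"]] * .hillRep(B, th[["B,F"]], n)
  list(c(dA, dB, dC, dE, dF))
}

.integrate <- function(rhs, y0, tGrid, params, rtol = 1e-8, atol = 1e-10) {
  out <- deSolve::ode(y = y0, times = tGrid, func = rhs, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed for the requested parameter point")
  out
}

#' Simulate the six-gene ground-truth oscillator
#'
#' Integrates the six-variable Hill system (unit decay, Hill exponent 5)
#' at one of the three stored parameterisations and samples it on
#' \code{tGrid}.  Optionally appends the spurious sinusoid gene G.
#'
#' @param column parameterisation 1, 2 or 3.
#' @param tGrid strictly increasing sampling times; the default covers
#'   several oscillation periods so that the second half is post-transient.
#' @param x0 initial state for (A, ..., F); default all 1.
#' @param addSpurious append the spurious gene G (see
#'   \code{\link{spuriousWave}}).
#' @param omega angular frequency of G.
#' @param rtol,atol solver tolerances.
#' @return a \linkS4class{TimeSeriesSet} with genes A-F (and optionally G).
#' @export
simulateGroundTruth <- function(column, tGrid = seq(0, 75, by = 0.25),
                                x0 = rep(1, 6), addSpurious = FALSE,
                                omega = 4.5 * pi,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(diff(tGrid) > 0), length(x0) == 6)
  p <- groundTruthParams(column)
  y0 <- setNames(x0, c("A", "B", "C", "D", "E", "F"))
  out <- .integrate(.gtRhs, y0, tGrid, p, rtol, atol)
  vals <- t(out[, -1, drop = FALSE])
  if (addSpurious)
    vals <- rbind(vals, G = spuriousWave(tGrid, omega))
  TimeSeriesSet(vals, tGrid, paste0("synthetic_col", column))
}

#' Simulate the five-gene reduction (node D removed)
#'
#' The five-variable system obtained by removing node D: C's equation
#' loses its repression factor and D's equation is dropped.  Under
#' parameterisation 1 the reduction kills the oscillation; under
#' parameterisation 3 strong oscillation persists.
#'
#' @inheritParams simulateGroundTruth
#' @param x0 initial state for (A, B, C, E, F); default all 1.
#' @return a \linkS4class{TimeSeriesSet} with genes A, B, C, E, F.
#' @export
simulateReduced <- function(column, tGrid = seq(0, 75, by = 0.25),
                            x0 = rep(1, 5), rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(diff(tGrid) > 0), length(x0) == 5)
  p <- groundTruthParams(column)
  y0 <- setNames(x0, c("A", "B", "C", "E", "F"))
  out <- .integrate(.gtRhsReduced, y0, tGrid, p, rtol, atol)
  TimeSeriesSet(t(out[, -1, drop = FALSE]), tGrid,
                paste0("reduced_col", column))
}

#' Spurious sinusoid gene
#'
#' \code{amplitude * (sin(omega * t) + 1)}: range [0, 2 * amplitude], mean
#' equal to \code{amplitude} over whole periods.  Represents a gene that
#' oscillates but participates in no regulation.
#'
#' @param tGrid sampling times.
#' @param omega angular frequency (> 0).
#' @param amplitude half-range of the wave.
#' @return numeric trace on \code{tGrid}.
#' @export
spuriousWave <- function(tGrid, omega = 4.5 * pi, amplitude = 2) {
  stopifnot(omega > 0)
  amplitude * (sin(omega * tGrid) + 1)
}

#' Minimum peak-to-trough fold change on the post-transient window
#'
#' @param tss a \linkS4class{TimeSeriesSet}.
#' @param transientFraction fraction of the time span discarded as
#'   transient (default the first half).
#' @return the minimum over genes of max/min on the retained window; the
#'   stored ground-truth simulations return >= 4 at all three
#'   parameterisations.
#' @export
foldChangeCheck <- function(tss, transientFraction = 0.5) {
  stopifnot(is(tss, "TimeSeriesSet"), transientFraction >= 0,
            transientFraction < 1)
  tcut <- tss@times[1] + transientFraction * diff(range(tss@times))
  keep <- tss@times >= tcut
  v <- tss@values[, keep, drop = FALSE]
  if (any(v <= 0)) stop("nonpositive trough on the post-transient window")
  min(apply(v, 1, max) / apply(v, 1, min))
}
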