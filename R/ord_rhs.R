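# Plain-R transcription of the O'Hara-Rudy dynamic (ORd) human ventricular
# epicardial cell model. This is the package's readable reference route: it is
# integrated with deSolve's stiff solvers and used to cross-check the compiled
# production engine. All units follow the ORd convention: mV, ms, mM, A/F.

#' State variable names of the ventricular cell model
#'
#' @return Character vector of the 41 state variable names, in the order used
#'   by [ord_initial_state()], [ord_rhs()] and the compiled engine.
#' @export
ord_state_names <- function() {
  c("v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
    "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
    "a", "iF", "iS", "ap", "iFp", "iSp",
    "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
    "xrf", "xrs", "xs1", "xs2", "xk1",
    "Jrelnp", "Jrelp", "CaMKt")
}

#' Baseline initial state of the epicardial model
#'
#' A resting-state vector close to the published steady state at a cycle
#' length of 1000 ms. Models are always paced to their own steady state before
#' analysis, so this vector only needs to be a sane starting point.
#'
#' @return Named numeric vector of length 41.
#' @export
ord_initial_state <- function() {
  s <- c(
    v = -87.5, nai = 7.23, nass = 7.23, ki = 143.79, kss = 143.79,
    cai = 8.54e-5, cass = 8.43e-5, cansr = 1.61, cajsr = 1.56,
    m = 0.0074621, hf = 0.692591, hs = 0.692574, j = 0.692477,
    hsp = 0.448501, jp = 0.692413, mL = 0.000194015, hL = 0.496116,
    hLp = 0.265885, a = 0.00101185, iF = 0.999542, iS = 0.589579,
    ap = 0.000515567, iFp = 0.999542, iSp = 0.641861,
    d = 2.43015e-9, ff = 0.9999999, fs = 0.910671, fcaf = 0.9999999,
    fcas = 0.99982, jca = 0.999977, nca = 0.00267171, ffp = 0.9999999,
    fcafp = 0.9999999, xrf = 8.26608e-6, xrs = 0.453268, xs1 = 0.270492,
    xs2 = 0.0001963, xk1 = 0.996801, Jrelnp = 2.53943e-5,
    Jrelp = 3.17262e-7, CaMKt = 0.0124065
  )
  stopifnot(identical(names(s), ord_state_names()))
  s
}

# Physical constants and epicardial cell geometry (ORd conventions, including
# the literal 3.14 used by the published code for cell volume/area).
.ord_const <- local({
  Rgas <- 8314; Temp <- 310; Frdy <- 96485
  L <- 0.01; rad <- 0.0011
  vcell <- 1000 * 3.14 * rad * rad * L
  Ageo <- 2 * 3.14 * rad * rad + 2 * 3.14 * rad * L
  Acap <- 2 * Ageo
  list(
    nao = 140, cao = 1.8, ko = 5.4,
    R = Rgas, T = Temp, F = Frdy,
    vcell = vcell, Acap = Acap,
    vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
    vjsr = 0.0048 * vcell, vss = 0.02 * vcell,
    # CaMKII
    aCaMK = 0.05, bCaMK = 0.00068, CaMKo = 0.05,
    KmCaM = 0.0015, KmCaMK = 0.15,
    # buffers (cmdnmax already carries the x1.3 epicardial scaling)
    cmdnmax = 0.05 * 1.3, kmcmdn = 0.00238,
    trpnmax = 0.07, kmtrpn = 0.0005,
    BSRmax = 0.047, KmBSR = 0.00087,
    BSLmax = 1.124, KmBSL = 0.0087,
    csqnmax = 10, kmcsqn = 0.8,
    # baseline maximal conductances/permeabilities with epicardial scalings
    GNa = 75, GNaL = 0.0075 * 0.6, Gto = 0.02 * 4, PCa = 0.0001 * 1.2,
    GKr = 0.046 * 1.3, GKs = 0.0034 * 1.4, GK1 = 0.1908 * 1.2,
    Gncx = 0.0008 * 1.1, Pnak = 30 * 0.9, GKb = 0.003 * 0.6,
    PNab = 3.75e-10, PCab = 2.5e-8, GpCa = 0.0005
  )
})

#' Time derivative of the ventricular cell model state
#'
#' Evaluates every current, flux and state derivative of the epicardial ORd
#' model under multiplicative parameter scaling. This is the slow reference
#' route; population runs use the compiled engine, which implements the same
#' equations.
#'
#' @param state Named numeric state vector (see [ord_state_names()]).
#' @param scaling A `parameter_scaling` object (see [parameter_scaling()]).
#' @param kinetics A `kinetics_scaling` object (see [kinetics_scaling()]).
#' @param i_stim Stimulus current in A/F (negative = depolarizing).
#' @return List with `dstate` (named derivative vector), `currents` (named
#'   A/F values of all sarcolemmal currents) and `fluxes` (named mM/ms values
#'   of intracellular Ca fluxes, in their native compartment reference).
#' @export
ord_rhs <- function(state, scaling = parameter_scaling(),
                    kinetics = kinetics_scaling(), i_stim = 0) {
  k <- .ord_const
  s <- as.list(state)
  v <- s$v; nai <- s$nai; nass <- s$nass; ki <- s$ki; kss <- s$kss
  cai <- s$cai; cass <- s$cass; cansr <- s$cansr; cajsr <- s$cajsr

  vfrt <- v * k$F / (k$R * k$T)
  vffrt <- k$F * vfrt

  ENa <- (k$R * k$T / k$F) * log(k$nao / nai)
  EK <- (k$R * k$T / k$F) * log(k$ko / ki)
  EKs <- (k$R * k$T / k$F) * log((k$ko + 0.01833 * k$nao) /
                                   (ki + 0.01833 * nai))

  # CaMKII activity
  CaMKb <- k$CaMKo * (1 - s$CaMKt) / (1 + k$KmCaM / cass)
  CaMKa <- CaMKb + s$CaMKt
  dCaMKt <- k$aCaMK * CaMKb * (CaMKb + s$CaMKt) - k$bCaMK * s$CaMKt
  fp <- 1 / (1 + k$KmCaMK / CaMKa)  # fraction of phosphorylated channels

  # --- fast Na+ current ---
  mss <- 1 / (1 + exp(-(v + 39.57) / 9.871))
  tm <- 1 / (6.765 * exp((v + 11.64) / 34.77) +
               8.552 * exp(-(v + 77.42) / 5.955))
  hss <- 1 / (1 + exp((v + 82.90) / 6.086))
  thf <- 1 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                6.149 * exp((v + 0.5096) / 20.27))
  ths <- 1 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                0.3343 * exp((v + 5.730) / 56.66))
  Ahf <- 0.99; Ahs <- 1 - Ahf
  h <- Ahf * s$hf + Ahs * s$hs
  jss <- hss
  tj <- 2.038 + 1 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                       0.3052 * exp((v + 0.9941) / 38.45))
  hssp <- 1 / (1 + exp((v + 89.1) / 6.086))
  thsp <- 3 * ths
  hp <- Ahf * s$hf + Ahs * s$hsp
  tjp <- 1.46 * tj
  INa <- scaling[["s_GNa"]] * k$GNa * (v - ENa) * s$m^3 *
    ((1 - fp) * h * s$j + fp * hp * s$jp)

  # --- late Na+ current ---
  mLss <- 1 / (1 + exp(-(v + 42.85) / 5.264))
  tmL <- tm
  hLss <- 1 / (1 + exp((v + 87.61) / 7.488))
  thL <- 200
  hLssp <- 1 / (1 + exp((v + 93.81) / 7.488))
  thLp <- 3 * thL
  INaL <- scaling[["s_GNaL"]] * k$GNaL * (v - ENa) * s$mL *
    ((1 - fp) * s$hL + fp * s$hLp)

  # --- transient outward K+ current (epicardial kinetics) ---
  ass <- 1 / (1 + exp(-(v - 14.34) / 14.82))
  ta <- 1.0515 / (1 / (1.2089 * (1 + exp(-(v - 18.4099) / 29.3814))) +
                    3.5 / (1 + exp((v + 100) / 29.3814)))
  iss <- 1 / (1 + exp((v + 43.94) / 5.711))
  delta_epi <- 1 - 0.95 / (1 + exp((v + 70) / 5))
  tiF <- (4.562 + 1 / (0.3933 * exp(-(v + 100) / 100) +
                         0.08004 * exp((v + 50) / 16.59))) * delta_epi
  tiS <- (23.62 + 1 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                         1.780e-8 * exp((v + 114.1) / 8.079))) * delta_epi
  AiF <- 1 / (1 + exp((v - 213.6) / 151.2))
  AiS <- 1 - AiF
  i_gate <- AiF * s$iF + AiS * s$iS
  assp <- 1 / (1 + exp(-(v - 24.34) / 14.82))
  dti_develop <- 1.354 + 1e-4 / (exp((v - 167.4) / 15.89) +
                                   exp(-(v - 12.23) / 0.2154))
  dti_recover <- 1 - 0.5 / (1 + exp((v + 70) / 20))
  tiFp <- dti_develop * dti_recover * tiF
  tiSp <- dti_develop * dti_recover * tiS
  ip_gate <- AiF * s$iFp + AiS * s$iSp
  Ito <- scaling[["s_Gto"]] * k$Gto * (v - EK) *
    ((1 - fp) * s$a * i_gate + fp * s$ap * ip_gate)

  # --- L-type Ca2+ current (and its Na+/K+ components) ---
  dss <- 1 / (1 + exp(-(v + 3.940) / 4.230))
  td <- kinetics[["m_tau_d"]] *
    (0.6 + 1 / (exp(-0.05 * (v + 6)) + exp(0.09 * (v + 14))))
  fss <- 1 / (1 + exp((v + 19.58) / 3.696))
  tff <- kinetics[["m_tau_f"]] *
    (7 + 1 / (0.0045 * exp(-(v + 20) / 10) + 0.0045 * exp((v + 20) / 10)))
  tfs <- kinetics[["m_tau_f"]] *
    (1000 + 1 / (3.5e-5 * exp(-(v + 5) / 4) + 3.5e-5 * exp((v + 5) / 6)))
  Aff <- 0.6; Afs <- 1 - Aff
  f <- Aff * s$ff + Afs * s$fs
  fcass <- fss
  tfcaf <- 7 + 1 / (0.04 * exp(-(v - 4) / 7) + 0.04 * exp((v - 4) / 7))
  tfcas <- 100 + 1 / (0.00012 * exp(-v / 3) + 0.00012 * exp(v / 7))
  Afcaf <- 0.3 + 0.6 / (1 + exp((v - 10) / 10))
  Afcas <- 1 - Afcaf
  fca <- Afcaf * s$fcaf + Afcas * s$fcas
  tjca <- kinetics[["m_tau_j"]] * 75
  jcass <- fss
  tffp <- 2.5 * tff
  f_p <- Aff * s$ffp + Afs * s$fs
  tfcafp <- 2.5 * tfcaf
  fca_p <- Afcaf * s$fcafp + Afcas * s$fcas
  Kmn <- 0.002; k2n <- 1000
  km2n <- s$jca * 1.0
  anca <- 1 / (k2n / km2n + (1 + Kmn / cass)^4)
  dnca <- anca * k2n - s$nca * km2n
  PhiCaL <- 4 * vffrt * (cass * exp(2 * vfrt) - 0.341 * k$cao) /
    (exp(2 * vfrt) - 1)
  PhiCaNa <- vffrt * (0.75 * nass * exp(vfrt) - 0.75 * k$nao) /
    (exp(vfrt) - 1)
  PhiCaK <- vffrt * (0.75 * kss * exp(vfrt) - 0.75 * k$ko) /
    (exp(vfrt) - 1)
  PCa <- scaling[["s_GCaL"]] * k$PCa
  PCap <- 1.1 * PCa
  PCaNa <- 0.00125 * PCa; PCaK <- 3.574e-4 * PCa
  PCaNap <- 0.00125 * PCap; PCaKp <- 3.574e-4 * PCap
  gate_np <- s$d * (f * (1 - s$nca) + s$jca * fca * s$nca)
  gate_p <- s$d * (f_p * (1 - s$nca) + s$jca * fca_p * s$nca)
  ICaL <- (1 - fp) * PCa * PhiCaL * gate_np + fp * PCap * PhiCaL * gate_p
  ICaNa <- (1 - fp) * PCaNa * PhiCaNa * gate_np + fp * PCaNap * PhiCaNa * gate_p
  ICaK <- (1 - fp) * PCaK * PhiCaK * gate_np + fp * PCaKp * PhiCaK * gate_p

  # --- rapid delayed rectifier ---
  xrss <- 1 / (1 + exp(-(v + 8.337) / 6.789))
  txrf <- 12.98 + 1 / (0.3652 * exp((v - 31.66) / 3.869) +
                         4.123e-5 * exp(-(v - 47.78) / 20.38))
  txrs <- 1.865 + 1 / (0.06629 * exp((v - 34.70) / 7.355) +
                         1.128e-5 * exp(-(v - 29.74) / 25.94))
  Axrf <- 1 / (1 + exp((v + 54.81) / 38.21))
  Axrs <- 1 - Axrf
  xr <- Axrf * s$xrf + Axrs * s$xrs
  rkr <- 1 / ((1 + exp((v + 55) / 75)) * (1 + exp((v - 10) / 30)))
  IKr <- scaling[["s_GKr"]] * k$GKr * sqrt(k$ko / 5.4) * xr * rkr * (v - EK)

  # --- slow delayed rectifier ---
  xs1ss <- 1 / (1 + exp(-(v + 11.60) / 8.932))
  txs1 <- 817.3 + 1 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                         0.001292 * exp(-(v + 210) / 230))
  xs2ss <- xs1ss
  txs2 <- 1 / (0.01 * exp((v - 50) / 20) + 0.0193 * exp(-(v + 66.54) / 31))
  KsCa <- 1 + 0.6 / (1 + (3.8e-5 / cai)^1.4)
  IKs <- scaling[["s_GKs"]] * k$GKs * KsCa * s$xs1 * s$xs2 * (v - EKs)

  # --- inward rectifier ---
  xk1ss <- 1 / (1 + exp(-(v + 2.5538 * k$ko + 144.59) /
                          (1.5692 * k$ko + 3.8115)))
  txk1 <- 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33))
  rk1 <- 1 / (1 + exp((v + 105.8 - 2.6 * k$ko) / 9.493))
  IK1 <- scaling[["s_GK1"]] * k$GK1 * sqrt(k$ko) * rk1 * s$xk1 * (v - EK)

  # --- Na+/Ca2+ exchanger (myoplasmic and subspace components) ---
  ncx <- function(na, ca) {
    kna1 <- 15; kna2 <- 5; kna3 <- 88.12; kasymm <- 12.5
    wna <- 6e4; wca <- 6e4; wnaca <- 5e3
    kcaon <- 1.5e6; kcaoff <- 5e3
    qna <- 0.5224; qca <- 0.1670
    hca <- exp(qca * vfrt); hna <- exp(qna * vfrt)
    h1 <- 1 + na / kna3 * (1 + hna)
    h2 <- (na * hna) / (kna3 * h1)
    h3 <- 1 / h1
    h4 <- 1 + na / kna1 * (1 + na / kna2)
    h5 <- na * na / (h4 * kna1 * kna2)
    h6 <- 1 / h4
    h7 <- 1 + k$nao / kna3 * (1 + 1 / hna)
    h8 <- k$nao / (kna3 * hna * h7)
    h9 <- 1 / h7
    h10 <- kasymm + 1 + k$nao / kna1 * (1 + k$nao / kna2)
    h11 <- k$nao * k$nao / (h10 * kna1 * kna2)
    h12 <- 1 / h10
    k1 <- h12 * k$cao * kcaon; k2 <- kcaoff
    k3p <- h9 * wca; k3pp <- h8 * wnaca; k3 <- k3p + k3pp
    k4p <- h3 * wca / hca; k4pp <- h2 * wnaca; k4 <- k4p + k4pp
    k5 <- kcaoff; k6 <- h6 * ca * kcaon
    k7 <- h5 * h2 * wna; k8 <- h8 * h11 * wna
    x1 <- k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3)
    x2 <- k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8)
    x3 <- k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3)
    x4 <- k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8)
    tot <- x1 + x2 + x3 + x4
    E1 <- x1 / tot; E2 <- x2 / tot; E3 <- x3 / tot; E4 <- x4 / tot
    KmCaAct <- 150e-6
    allo <- 1 / (1 + (KmCaAct / ca)^2)
    JncxNa <- 3 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp
    JncxCa <- E2 * k2 - E1 * k1
    allo * (1 * JncxNa + 2 * JncxCa)
  }
  Gncx <- scaling[["s_GNaCa"]] * k$Gncx
  INaCa_i <- 0.8 * Gncx * ncx(nai, cai)
  INaCa_ss <- 0.2 * Gncx * ncx(nass, cass)

  # --- Na+/K+ pump ---
  k1p <- 949.5; k1m <- 182.4; k2p <- 687.2; k2m <- 39.4
  k3p_ <- 1899; k3m <- 79300; k4p_ <- 639; k4m <- 40
  Knai0 <- 9.073; Knao0 <- 27.78; delta <- -0.1550
  Knai <- Knai0 * exp(delta * vfrt / 3)
  Knao <- Knao0 * exp((1 - delta) * vfrt / 3)
  Kki <- 0.5; Kko <- 0.3582; MgADP <- 0.05; MgATP <- 9.8
  Kmgatp <- 1.698e-7; H <- 1e-7; eP <- 4.2; Khp <- 1.698e-7
  Knap <- 224; Kxkur <- 292
  P <- eP / (1 + H / Khp + nai / Knap + ki / Kxkur)
  a1 <- k1p * (nai / Knai)^3 /
    ((1 + nai / Knai)^3 + (1 + ki / Kki)^2 - 1)
  b1 <- k1m * MgADP
  a2 <- k2p
  b2 <- k2m * (k$nao / Knao)^3 /
    ((1 + k$nao / Knao)^3 + (1 + k$ko / Kko)^2 - 1)
  a3 <- k3p_ * (k$ko / Kko)^2 /
    ((1 + k$nao / Knao)^3 + (1 + k$ko / Kko)^2 - 1)
  b3 <- k3m * P * H / (1 + MgATP / Kmgatp)
  a4 <- k4p_ * MgATP / Kmgatp / (1 + MgATP / Kmgatp)
  b4 <- k4m * (ki / Kki)^2 /
    ((1 + nai / Knai)^3 + (1 + ki / Kki)^2 - 1)
  x1 <- a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2
  x2 <- b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4
  x3 <- a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1
  x4 <- b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b1 * a1
  tot <- x1 + x2 + x3 + x4
  E1 <- x1 / tot; E2 <- x2 / tot; E3 <- x3 / tot; E4 <- x4 / tot
  JnakNa <- 3 * (E1 * a3 - E2 * b3)
  JnakK <- 2 * (E4 * b1 - E3 * a1)
  INaK <- scaling[["s_GNaK"]] * k$Pnak * (1 * JnakNa + 1 * JnakK)

  # --- background and pump currents ---
  xkb <- 1 / (1 + exp(-(v - 14.48) / 18.34))
  IKb <- k$GKb * xkb * (v - EK)
  INab <- k$PNab * vffrt * (nai * exp(vfrt) - k$nao) / (exp(vfrt) - 1)
  ICab <- k$PCab * 4 * vffrt * (cai * exp(2 * vfrt) - 0.341 * k$cao) /
    (exp(2 * vfrt) - 1)
  IpCa <- k$GpCa * cai / (0.0005 + cai)

  # --- intracellular fluxes ---
  JdiffNa <- (nass - nai) / 2
  JdiffK <- (kss - ki) / 2
  Jdiff <- (cass - cai) / 0.2

  bt <- 4.75
  a_rel <- 0.5 * bt
  Jrel_inf <- a_rel * (-ICaL) / (1 + (1.5 / cajsr)^8)
  tau_rel <- bt / (1 + 0.0123 / cajsr)
  tau_rel <- max(tau_rel, 0.001)
  dJrelnp <- (Jrel_inf - s$Jrelnp) / tau_rel
  btp <- 1.25 * bt
  a_relp <- 0.5 * btp
  Jrel_infp <- a_relp * (-ICaL) / (1 + (1.5 / cajsr)^8)
  tau_relp <- btp / (1 + 0.0123 / cajsr)
  tau_relp <- max(tau_relp, 0.001)
  dJrelp <- (Jrel_infp - s$Jrelp) / tau_relp
  Jrel <- scaling[["s_PJrel"]] *
    ((1 - fp) * s$Jrelnp + fp * s$Jrelp)

  Jupnp <- 0.004375 * cai / (cai + 0.00092)
  Jupp <- 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017)
  Jleak <- 0.0039375 * cansr / 15
  Jup <- scaling[["s_PJup"]] * ((1 - fp) * Jupnp + fp * Jupp) - Jleak

  Jtr <- (cansr - cajsr) / 100

  # --- concentration derivatives ---
  AF <- k$Acap / k$F
  dnai <- -(INa + INaL + 3 * INaCa_i + 3 * INaK + INab) * AF / k$vmyo +
    JdiffNa * k$vss / k$vmyo
  dnass <- -(ICaNa + 3 * INaCa_ss) * AF / k$vss - JdiffNa
  dki <- -(Ito + IKr + IKs + IK1 + IKb + i_stim - 2 * INaK) * AF / k$vmyo +
    JdiffK * k$vss / k$vmyo
  dkss <- -ICaK * AF / k$vss - JdiffK
  Bcai <- 1 / (1 + k$cmdnmax * k$kmcmdn / (k$kmcmdn + cai)^2 +
                 k$trpnmax * k$kmtrpn / (k$kmtrpn + cai)^2)
  dcai <- Bcai * (-(IpCa + ICab - 2 * INaCa_i) * AF / (2 * k$vmyo) -
                    Jup * k$vnsr / k$vmyo + Jdiff * k$vss / k$vmyo)
  Bcass <- 1 / (1 + k$BSRmax * k$KmBSR / (k$KmBSR + cass)^2 +
                  k$BSLmax * k$KmBSL / (k$KmBSL + cass)^2)
  dcass <- Bcass * (-(ICaL - 2 * INaCa_ss) * AF / (2 * k$vss) +
                      Jrel * k$vjsr / k$vss - Jdiff)
  dcansr <- Jup - Jtr * k$vjsr / k$vnsr
  Bcajsr <- 1 / (1 + k$csqnmax * k$kmcsqn / (k$kmcsqn + cajsr)^2)
  dcajsr <- Bcajsr * (Jtr - Jrel)

  Iion <- INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
    INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab
  dv <- -(Iion + i_stim)

  # --- gate derivatives ---
  dstate <- c(
    v = dv, nai = dnai, nass = dnass, ki = dki, kss = dkss,
    cai = dcai, cass = dcass, cansr = dcansr, cajsr = dcajsr,
    m = (mss - s$m) / tm,
    hf = (hss - s$hf) / thf,
    hs = (hss - s$hs) / ths,
    j = (jss - s$j) / tj,
    hsp = (hssp - s$hsp) / thsp,
    jp = (jss - s$jp) / tjp,
    mL = (mLss - s$mL) / tmL,
    hL = (hLss - s$hL) / thL,
    hLp = (hLssp - s$hLp) / thLp,
    a = (ass - s$a) / ta,
    iF = (iss - s$iF) / tiF,
    iS = (iss - s$iS) / tiS,
    ap = (assp - s$ap) / ta,
    iFp = (iss - s$iFp) / tiFp,
    iSp = (iss - s$iSp) / tiSp,
    d = (dss - s$d) / td,
    ff = (fss - s$ff) / tff,
    fs = (fss - s$fs) / tfs,
    fcaf = (fcass - s$fcaf) / tfcaf,
    fcas = (fcass - s$fcas) / tfcas,
    jca = (jcass - s$jca) / tjca,
    nca = dnca,
    ffp = (fss - s$ffp) / tffp,
    fcafp = (fcass - s$fcafp) / tfcafp,
    xrf = (xrss - s$xrf) / txrf,
    xrs = (xrss - s$xrs) / txrs,
    xs1 = (xs1ss - s$xs1) / txs1,
    xs2 = (xs2ss - s$xs2) / txs2,
    xk1 = (xk1ss - s$xk1) / txk1,
    Jrelnp = dJrelnp,
    Jrelp = dJrelp,
    CaMKt = dCaMKt
  )

  list(
    dstate = dstate,
    currents = c(INa = INa, INaL = INaL, Ito = Ito, ICaL = ICaL,
                 ICaNa = ICaNa, ICaK = ICaK, IKr = IKr, IKs = IKs,
                 IK1 = IK1, INaCa_i = INaCa_i, INaCa_ss = INaCa_ss,
                 INaK = INaK, INab = INab, IKb = IKb, IpCa = IpCa,
                 ICab = ICab, Istim = i_stim),
    fluxes = c(Jrel = Jrel, Jup = Jup, Jleak = Jleak, Jtr = Jtr,
               Jdiff = Jdiff, JdiffNa = JdiffNa, JdiffK = JdiffK)
  )
}

#' Cell geometry and physical constants
#'
#' @return Named list of the physical constants, compartment volumes (uL) and
#'   capacitive membrane area (cm^2) used by both model transcriptions.
#' @export
ord_constants <- function() .ord_const

#' Total calcium content of the cell
#'
#' Free plus buffer-bound calcium in every compartment, volume weighted and
#' expressed per litre of cytosol. Used by conservation tests: in the absence
#' of net sarcolemmal Ca flux this quantity is constant.
#'
#' @param state Named state vector.
#' @return Total Ca in mM (per litre cytosol).
#' @export
ord_total_ca <- function(state) {
  k <- .ord_const
  s <- as.list(state)
  cmdn <- k$cmdnmax * s$cai / (k$kmcmdn + s$cai)
  trpn <- k$trpnmax * s$cai / (k$kmtrpn + s$cai)
  bsr <- k$BSRmax * s$cass / (k$KmBSR + s$cass)
  bsl <- k$BSLmax * s$cass / (k$KmBSL + s$cass)
  csqn <- k$csqnmax * s$cajsr / (k$kmcsqn + s$cajsr)
  ((s$cai + cmdn + trpn) * k$vmyo +
      (s$cass + bsr + bsl) * k$vss +
      s$cansr * k$vnsr +
      (s$cajsr + csqn) * k$vjsr) / k$vmyo
}
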