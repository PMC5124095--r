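.carbonateConstants <- function(temperatureC, salinity) {
  TK <- temperatureC + 273.15
  S <- salinity
  lnTK <- log(TK)
  IonS <- 19.924 * S / (1000 - 1.005 * S)
  TB <- 0.0004157 * S / 35
  TS <- (0.14 / 96.062) * (S / 1.80655)
  TF <- (0.000067 / 18.998) * (S / 1.80655)
  # CO2 solubility, Weiss 1974, mol kg^-1 atm^-1
  K0 <- exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
              S * (0.023517 - 0.023656 * (TK / 100) +
                     0.0047036 * (TK / 100)^2))
  # carbonic acid, Lueker et al. 2000, total scale
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnTK - 0.011555 * S +
    0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * lnTK - 0.01781 * S +
    0.0001122 * S^2
  # boric acid, Dickson 1990, total scale
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lnTK +
    0.053105 * sqrt(S) * TK
  # water, Millero 1995 (SWS scale, converted below)
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnTK +
    (-5.977 + 118.67 / TK + 1.0495 * lnTK) * sqrt(S) - 0.01615 * S
  # bisulfate, Dickson 1990 (free scale)
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnTK +
    (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IonS) +
    (35474 / TK - 771.54 + 114.723 * lnTK) * IonS -
    2698 / TK * IonS^1.5 + 1776 / TK * IonS^2 + log(1 - 0.001005 * S)
  # hydrogen fluoride, Dickson & Riley 1979 (free scale)
  lnKF <- 1590.2 / TK - 12.641 + 1.525 * sqrt(IonS) + log(1 - 0.001005 * S)
  KS <- exp(lnKS)
  KF <- exp(lnKF)
  FREEtoTOT <- 1 + TS / KS
  SWStoTOT <- (1 + TS / KS) / (1 + TS / KS + TF / KF)
  # aragonite solubility, Mucci 1983
  logKspA <- -171.945 - 0.077993 * TK + 2903.293 / TK +
    71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(S) -
    0.10018 * S + 0.0059415 * S^1.5
  # CO2 fugacity coefficient at 1 atm total pressure, Weiss 1974
  b <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
  Delta <- 57.7 - 0.118 * TK
  FugFac <- exp((b + 2 * Delta) * 1.01325 / (83.1451 * TK))
  list(K0 = K0, K1 = 10^-pK1, K2 = 10^-pK2, KB = exp(lnKB),
       KW = exp(lnKW) * SWStoTOT, KS = KS, KF = KF,
       TB = TB, TS = TS, TF = TF, FREEtoTOT = FREEtoTOT,
       KspA = 10^logKspA, Ca = 0.02128 / 40.087 * (S / 1.80655),
       FugFac = FugFac)
}

.totalAlkalinity <- function(H, dic, k) {
  denom <- H^2 + k$K1 * H + k$K1 * k$K2
  hco3 <- dic * k$K1 * H / denom
  co3 <- dic * k$K1 * k$K2 / denom
  balk <- k$TB * k$KB / (k$KB + H)
  hFree <- H / k$FREEtoTOT
  hco3 + 2 * co3 + balk + k$KW / H - hFree -
    k$TS / (1 + k$KS / hFree) - k$TF / (1 + k$KF / hFree)
}

#' Solve the seawater carbonate system from total alkalinity and DIC
#'
#' Finds the equilibrium pH (total scale) whose speciation reproduces the
#' measured total alkalinity at the given DIC, temperature and salinity,
#' then reports pCO2 and the aragonite saturation state. Constants: Lueker
#' et al. (2000) carbonic acid (total scale), Dickson (1990) boric acid and
#' bisulfate, Dickson & Riley (1979) fluoride, Millero (1995) water, Weiss
#' (1974) CO2 solubility and fugacity, Mucci (1983) aragonite solubility,
#' Uppstrom boron-to-salinity -- the conventional choice for tropical
#' open-ocean seawater.
#'
#' @param aT total alkalinity, umol kg^-1 (vectorized).
#' @param dic dissolved inorganic carbon, umol kg^-1.
#' @param temperatureC in-situ temperature, degrees C (15-35).
#' @param salinity practical salinity (20-40).
#' @return data.frame with columns ph_total, pco2_uatm, omega_arag,
#'   co3_umol_kg, a_t, dic, temperature_c, salinity. At fixed T and S,
#'   omega_arag is proportional to the carbonate-ion concentration, and pH
#'   strictly decreases as DIC rises at fixed alkalinity.
#' @examples
#' solveCarbonateSystem(2300, 1900, 29, 35)$ph_total
#' @export
solveCarbonateSystem <- function(aT, dic, temperatureC, salinity) {
  n <- max(length(aT), length(dic), length(temperatureC), length(salinity))
  aT <- rep_len(aT, n); dic <- rep_len(dic, n)
  temperatureC <- rep_len(temperatureC, n)
  salinity <- rep_len(salinity, n)
  if (any(salinity < 20 | salinity > 40))
    stop("salinity outside the supported seawater range 20-40")
  if (any(temperatureC < 15 | temperatureC > 35))
    stop("temperature outside the supported range 15-35 C")
  out <- lapply(seq_len(n), function(i) {
    k <- .carbonateConstants(temperatureC[i], salinity[i])
    at <- aT[i] * 1e-6
    ct <- dic[i] * 1e-6
    root <- tryCatch(
      stats::uniroot(function(pH) .totalAlkalinity(10^-pH, ct, k) - at,
                     interval = c(3, 12), tol = 1e-12),
      error = function(e)
        stop("carbonate-system pH solve failed to converge: ",
             conditionMessage(e)))
    pH <- root$root
    H <- 10^-pH
    denom <- H^2 + k$K1 * H + k$K1 * k$K2
    co2 <- ct * H^2 / denom
    co3 <- ct * k$K1 * k$K2 / denom
    data.frame(ph_total = pH,
               pco2_uatm = co2 / k$K0 / k$FugFac * 1e6,
               omega_arag = k$Ca * co3 / k$KspA,
               co3_umol_kg = co3 * 1e6,
               a_t = aT[i], dic = dic[i],
               temperature_c = temperatureC[i], salinity = salinity[i])
  })
  do.call(rbind, out)
}
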