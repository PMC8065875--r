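## Forward signal model: Patlak concentration dynamics, extra-cerebral
## enhancement curves, linear relaxation-rate modulation and spoiled
## gradient echo signal synthesis.

#' Patlak tissue concentration time course
#'
#' C_t[t] = vP * c_p[t] + PS * integral(c_p, 0..t), the linear
#' irreversible-leakage model appropriate to the slow-leakage regime at low
#' temporal resolution. The integral is evaluated by the cumulative
#' trapezoidal rule on the supplied times, the same quadrature used by
#' \code{\link{patlakFit}}, so that fitting forward-model output is exact.
#'
#' @param vP plasma volume fraction (dimensionless, in [0, 1]).
#' @param PS permeability-surface area product, per minute.
#' @param aif an \linkS4class{AIF}.
#' @param timesS frame times in s (strictly increasing).
#' @param allowNegative permit negative vP or PS (the forward model rejects
#'   them by default; fitting can produce them).
#' @return tissue concentration in mM at each time.
#' @export
patlakConcentration <- function(vP, PS, aif, timesS, allowNegative = FALSE) {
  if (!allowNegative && (vP < 0 || PS < 0))
    stop("negative vP or PS in the forward model (set allowNegative to override)")
  if (is.unsorted(timesS, strictly = TRUE)) stop("times must be strictly increasing")
  cp <- aifConcentration(aif, timesS)
  vP * cp + PS * cumtrapz(cp, timesS / 60)
}

#' Extra-cerebral signal enhancement curve
#'
#' Relative signal multiplier for tissues without a blood-brain barrier
#' (muscle, skin, marrow, ...), whose enhancement is far larger than that of
#' brain tissue and is modelled directly on the signal rather than through
#' the Patlak model. Equals 1 before bolus arrival.
#'
#' Forms: \code{"exponential"} saturation E(t) = 1 + a (1 - exp(-t'/tau_s));
#' \code{"power"} E(t) = 1 + b (t'/tref_s)^p; \code{"constant"} E = 1;
#' with t' the time since onset.
#'
#' @param params list with \code{form} and its parameters
#'   (\code{a}, \code{tau_s} or \code{b}, \code{p}, \code{tref_s}).
#' @param timesS frame times in s.
#' @param onsetS bolus arrival time in s.
#' @return enhancement multiplier per frame.
#' @export
extracerebralEnhancement <- function(params, timesS, onsetS = 0) {
  form <- params$form %||% "constant"
  tp <- pmax(timesS - onsetS, 0)
  E <- switch(form,
    constant = rep(1, length(timesS)),
    exponential = {
      if (!is.finite(params$a) || !is.finite(params$tau_s))
        stop("non-finite enhancement parameters")
      1 + params$a * (1 - exp(-tp / params$tau_s))
    },
    power = {
      if (!all(is.finite(c(params$b, params$p, params$tref_s))))
        stop("non-finite enhancement parameters")
      1 + params$b * (tp / params$tref_s)^params$p
    },
    stop("unknown enhancement form: ", form))
  E[timesS < onsetS] <- 1
  E
}

#' Contrast-induced relaxation rate change
#'
#' 1/Ti[t] = 1/Ti0 + ri * C_t[t] for i in {1, 2*}: relaxation rates vary
#' linearly with the gadolinium concentration.
#'
#' @param C concentration in mM (vector or array).
#' @param T10,T2star0 pre-contrast relaxation times, s.
#' @param r1,r2star relaxivities, per mM per s.
#' @return list with elements \code{T1} and \code{T2star} (s), same shape
#'   as \code{C}.
#' @export
relaxationRates <- function(C, T10, T2star0, r1, r2star) {
  stopifnot(all(T10 > 0), all(T2star0 > 0))
  list(T1 = 1 / (1 / T10 + r1 * C),
       T2star = 1 / (1 / T2star0 + r2star * C))
}

#' Spoiled gradient echo steady-state signal
#'
#' S = S0 (1 - e^(-TR/T1)) sin(theta) / (1 - e^(-TR/T1) cos(theta))
#'     * e^(-TE/T2*).
#'
#' @param S0 equilibrium signal (arbitrary units).
#' @param T1,T2star relaxation times in s (vectors/arrays recycle).
#' @param proto an \linkS4class{MRProtocol} supplying TR, TE and flip angle.
#' @return signal in the units of \code{S0}.
#' @export
spgrSignal <- function(S0, T1, T2star, proto) {
  th <- proto@flipDeg * pi / 180
  E1 <- exp(-proto@tr / T1)
  S0 * (1 - E1) * sin(th) / (1 - E1 * cos(th)) * exp(-proto@te / T2star)
}

## T1-dependent part of the SPGR signal (no S0, no T2* factor); used by the
## concentration inversion.
spgrSaturation <- function(T1, proto) {
  th <- proto@flipDeg * pi / 180
  E1 <- exp(-proto@tr / T1)
  (1 - E1) * sin(th) / (1 - E1 * cos(th))
}

#' Per-class signal-time curves
#'
#' Computes the time-signal curve of every tissue class in the table under
#' the protocol: brain classes and vessels follow Patlak concentration ->
#' relaxation-rate modulation -> SPGR; extra-cerebral classes scale their
#' pre-contrast SPGR signal by their enhancement curve; \code{"none"}
#' classes stay flat. Because tissue parameters are piecewise-constant per
#' class, these curves fully determine the high-resolution 4D object.
#'
#' @param table a \code{\link{tissueParameterTable}}.
#' @param aif an \linkS4class{AIF}.
#' @param proto an \linkS4class{MRProtocol}.
#' @param hct haematocrit (vessel vP = 1 - hct).
#' @param extracerebralOn if \code{FALSE}, extra-cerebral classes keep their
#'   pre-contrast signal for all frames (the enhancement-disabled
#'   experiment).
#' @return matrix of dimension (max class ID + 1) x nFrames; row 1 is the
#'   background (zero signal), row id+1 belongs to class id.
#' @export
tissueSignalTable <- function(table, aif, proto, hct = 0.45,
                              extracerebralOn = TRUE) {
  tS <- frameTimes(proto)
  tab <- as.data.frame(table)
  tab$vP[tab$name == "vessels"] <- 1 - hct
  S <- matrix(0, nrow = max(tab$class_id) + 1, ncol = length(tS))
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    base <- spgrSignal(row$S0, row$T10_s, row$T2star0_s, proto)
    curve <- switch(row$enhancement_mode,
      patlak = {
        Ct <- patlakConcentration(row$vP %||% 0, row$PS_per_min, aif, tS)
        rel <- relaxationRates(Ct, row$T10_s, row$T2star0_s,
                               proto@r1, proto@r2star)
        spgrSignal(row$S0, rel$T1, rel$T2star, proto)
      },
      extracerebral_curve = {
        if (extracerebralOn) {
          p <- jsonlite::fromJSON(row$curve_params)
          base * extracerebralEnhancement(p, tS, onsetS = aif@onsetS)
        } else rep(base, length(tS))
      },
      none = rep(base, length(tS)))
    S[row$class_id + 1, ] <- curve
  }
  S
}

#' Lazy per-frame synthesis of the high-resolution DRO
#'
#' Returns a function \code{f(i)} producing the high-resolution 3D signal
#' volume of frame \code{i}, so the full 4D object never needs to be held in
#' memory during acquisition simulation.
#'
#' @inheritParams tissueSignalTable
#' @param vol a \linkS4class{LabelVolume}.
#' @return function of the frame index returning a 3D array.
#' @export
droFrameFun <- function(vol, table, aif, proto, hct = 0.45,
                        extracerebralOn = TRUE) {
  S <- tissueSignalTable(table, aif, proto, hct, extracerebralOn)
  idx <- as.vector(vol@labels) + 1L
  d <- dim(vol@labels)
  function(i) array(S[idx, i], d)
}

#' Synthesize the high-resolution ground-truth 4D DRO
#'
#' Materialises every frame of \code{\link{droFrameFun}} into a
#' \linkS4class{DynamicVolume} on the source grid.
#'
#' @inheritParams droFrameFun
#' @return A \linkS4class{DynamicVolume}.
#' @export
synthesizeDRO <- function(vol, table, aif, proto, hct = 0.45,
                          extracerebralOn = TRUE) {
  f <- droFrameFun(vol, table, aif, proto, hct, extracerebralOn)
  n <- nFrames(proto)
  d <- dim(vol@labels)
  out <- array(0, c(d, n))
  for (i in seq_len(n)) out[, , , i] <- f(i)
  DynamicVolume(out, spacing = vol@spacing, frameTimes = frameTimes(proto),
                affine = vol@affine)
}
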