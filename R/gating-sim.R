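# Markov single-channel gating simulation and half-amplitude idealization.
#
# Units: rate constants per millisecond, unitary conductance in picosiemens,
# potentials in millivolts, currents in picoamperes, times in seconds unless
# a name says otherwise. The single-open-channel current is
#   i [pA] = gamma [pS] * (V - Vrev) [mV] / 1000.

#' GatingModel: Markov gating parameters for a channel population
#'
#' Two schemes are supported: a two-state channel C <-> O (rates \code{kCO},
#' \code{kOC}) and a three-state burst scheme C1 <-> C2 <-> O (additionally
#' \code{kC1C2}, \code{kC2C1}; openings occur from C2), which produces
#' bursts of openings separated by brief closures. Rates are per
#' millisecond. \code{nChannels} independent channels are superposed.
#'
#' @slot type \code{"two_state"} or \code{"burst"}.
#' @slot rates named numeric rate constants (per ms).
#' @slot nChannels integer >= 1.
#' @slot gamma unitary conductance, pS.
#' @slot vRev reversal potential, mV.
#' @slot noiseSd additive Gaussian noise SD, pA.
#' @slot sampleRate sampling rate, Hz (default 20000).
#' @slot filterCutoff low-pass -3 dB cutoff, Hz (default 2000).
#' @export
setClass("GatingModel",
  representation(type = "character", rates = "numeric",
                 nChannels = "integer", gamma = "numeric", vRev = "numeric",
                 noiseSd = "numeric", sampleRate = "numeric",
                 filterCutoff = "numeric"))

setValidity("GatingModel", function(object) {
  need <- if (object@type == "two_state") c("kCO", "kOC")
          else if (object@type == "burst") c("kCO", "kOC", "kC1C2", "kC2C1")
          else return("type must be 'two_state' or 'burst'")
  if (!all(need %in% names(object@rates)))
    return(paste("rates must include", paste(need, collapse = ", ")))
  if (any(object@rates[need] <= 0)) return("all rate constants must be > 0")
  if (object@nChannels < 1L) return("nChannels must be >= 1")
  po <- openProbability(object)
  if (po <= 0 || po >= 1) return("stationary open probability must lie in (0,1)")
  if (object@sampleRate <= 0) return("sampleRate must be positive")
  TRUE
})

setMethod("show", "GatingModel", function(object) {
  cat(sprintf("GatingModel (%s), N = %d, gamma = %g pS, Po = %.4f\n",
              object@type, object@nChannels, object@gamma,
              openProbability(object)))
  cat("  rates (/ms):",
      paste(names(object@rates), signif(object@rates, 4), sep = "=",
            collapse = ", "), "\n")
})

#' Construct a gating model
#'
#' @param kCO opening rate C->O (burst scheme: C2->O), per ms.
#' @param kOC closing rate O->C (burst: O->C2), per ms.
#' @param type \code{"two_state"} (default) or \code{"burst"}.
#' @param kC1C2,kC2C1 inter-closed rates for the burst scheme, per ms.
#' @param nChannels number of independent channels in the patch.
#' @param gamma unitary conductance, pS.
#' @param vRev reversal potential, mV.
#' @param noiseSd additive Gaussian noise SD, pA.
#' @param sampleRate sampling rate, Hz.
#' @param filterCutoff low-pass cutoff, Hz.
#' @return a \code{\linkS4class{GatingModel}}.
#' @export
gatingModel <- function(kCO, kOC, type = c("two_state", "burst"),
                        kC1C2 = NULL, kC2C1 = NULL, nChannels = 1L,
                        gamma = 20, vRev = 0, noiseSd = 0,
                        sampleRate = 20000, filterCutoff = 2000) {
  type <- match.arg(type)
  rates <- c(kCO = kCO, kOC = kOC)
  if (type == "burst") rates <- c(rates, kC1C2 = kC1C2, kC2C1 = kC2C1)
  new("GatingModel", type = type, rates = rates,
      nChannels = as.integer(nChannels), gamma = gamma, vRev = vRev,
      noiseSd = noiseSd, sampleRate = sampleRate,
      filterCutoff = filterCutoff)
}

#' Stationary single-channel open probability of a gating model
#' @param model a \code{\linkS4class{GatingModel}}.
#' @export
openProbability <- function(model) {
  r <- model@rates
  if (model@type == "two_state") {
    unname(r["kCO"] / (r["kCO"] + r["kOC"]))
  } else {
    # stationary distribution of C1 <-> C2 <-> O by detailed balance
    w1 <- 1
    w2 <- w1 * r[["kC1C2"]] / r[["kC2C1"]]
    wo <- w2 * r[["kCO"]] / r[["kOC"]]
    unname(wo / (w1 + w2 + wo))
  }
}

.stationaryDist <- function(model) {
  r <- model@rates
  if (model@type == "two_state") {
    po <- openProbability(model)
    c(C = 1 - po, O = po)
  } else {
    w <- c(C1 = 1, C2 = r[["kC1C2"]] / r[["kC2C1"]])
    w <- c(w, O = unname(w["C2"]) * r[["kCO"]] / r[["kOC"]])
    w / sum(w)
  }
}

# transition edges (from-state, to-state, rate per ms) and which states
# conduct
.modelEdges <- function(model) {
  r <- model@rates
  if (model@type == "two_state") {
    list(states = c("C", "O"), open = c(FALSE, TRUE),
         edges = data.frame(from = c(1L, 2L), to = c(2L, 1L),
                            rate = c(r[["kCO"]], r[["kOC"]])))
  } else {
    list(states = c("C1", "C2", "O"), open = c(FALSE, FALSE, TRUE),
         edges = data.frame(from = c(1L, 2L, 2L, 3L),
                            to = c(2L, 1L, 3L, 2L),
                            rate = c(r[["kC1C2"]], r[["kC2C1"]],
                                     r[["kCO"]], r[["kOC"]])))
  }
}

#' SimulatedTrace: a simulated patch-current recording
#'
#' Holds the sampled current, the per-sample true open-channel count, and
#' the exact continuous-time event path (jump times and open counts) the
#' samples were drawn from; the exact path is retained for testing and for
#' unbiased dwell statistics via \code{\link{trueEvents}}.
#'
#' @slot dt sample interval, s.
#' @slot samples current, pA.
#' @slot statePath per-sample open-channel count.
#' @slot eventTimes jump times, s (first is 0).
#' @slot eventLevels open-channel count after each jump.
#' @slot voltage command potential, mV.
#' @slot unitaryAmplitude single-open-channel current, pA.
#' @slot duration trace duration, s.
#' @slot seed RNG seed used.
#' @export
setClass("SimulatedTrace",
  representation(dt = "numeric", samples = "numeric", statePath = "integer",
                 eventTimes = "numeric", eventLevels = "integer",
                 voltage = "numeric", unitaryAmplitude = "numeric",
                 duration = "numeric", seed = "integer"))

setValidity("SimulatedTrace", function(object) {
  if (length(object@samples) != length(object@statePath))
    return("samples and statePath must have equal length")
  if (length(object@eventTimes) != length(object@eventLevels))
    return("eventTimes and eventLevels must have equal length")
  if (length(object@eventTimes) && object@eventTimes[1L] != 0)
    return("event path must start at time 0")
  TRUE
})

setMethod("show", "SimulatedTrace", function(object) {
  cat(sprintf(paste0("SimulatedTrace: %.3g s at %g kHz (%d samples), ",
                     "V = %g mV, i1 = %.3g pA\n"),
              object@duration, 1 / object@dt / 1000,
              length(object@samples), object@voltage,
              object@unitaryAmplitude))
})

# exact dwell simulation of the aggregated channel-count chain.
# Occupancy across states evolves by Gillespie jumps with propensity
# n[from] * rate; the per-channel chain starts from its stationary law so
# time averages match stationary expectations without burn-in.
.simulateJumps <- function(model, duration) {
  info <- .modelEdges(model)
  nStates <- length(info$states)
  N <- model@nChannels
  pstat <- .stationaryDist(model)
  occ <- as.vector(stats::rmultinom(1L, N, pstat))
  ratesPerSec <- info$edges$rate * 1000
  times <- numeric(0)
  levels <- integer(0)
  # grow in chunks to avoid O(n^2) appends
  cap <- 4096L
  times <- numeric(cap); levels <- integer(cap)
  k <- 1L
  times[1L] <- 0
  levels[1L] <- sum(occ[info$open])
  t <- 0
  while (TRUE) {
    prop <- occ[info$edges$from] * ratesPerSec
    tot <- sum(prop)
    if (tot <= 0) break
    t <- t + stats::rexp(1L, tot)
    if (t >= duration) break
    e <- sample.int(nrow(info$edges), 1L, prob = prop)
    occ[info$edges$from[e]] <- occ[info$edges$from[e]] - 1L
    occ[info$edges$to[e]] <- occ[info$edges$to[e]] + 1L
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(levels) <- cap
    }
    times[k] <- t
    levels[k] <- sum(occ[info$open])
  }
  list(times = times[seq_len(k)], levels = levels[seq_len(k)])
}

# fast path: a single two-state channel as alternating exponential dwells
.simulateTwoStateSingle <- function(model, duration) {
  r <- model@rates
  kCO <- r[["kCO"]] * 1000   # per second
  kOC <- r[["kOC"]] * 1000
  po <- openProbability(model)
  state <- as.integer(stats::runif(1L) < po)   # 1 = open
  # expected dwell pairs per record, with headroom
  chunk <- max(64L, ceiling(duration * kCO * kOC / (kCO + kOC) * 1.25))
  times <- 0
  levels <- state
  t <- 0
  repeat {
    # alternating dwells starting from the current state
    dA <- stats::rexp(chunk, if (state == 1L) kOC else kCO)
    dB <- stats::rexp(chunk, if (state == 1L) kCO else kOC)
    jt <- t + cumsum(as.vector(rbind(dA, dB)))
    lv <- rep(c(1L - state, state), chunk)
    keep <- jt < duration
    times <- c(times, jt[keep])
    levels <- c(levels, lv[keep])
    if (any(!keep)) break
    t <- jt[2L * chunk]  # state after an even number of dwells is unchanged
  }
  list(times = times, levels = levels)
}

#' Simulate a patch-current trace from a gating model
#'
#' Exact stochastic jump simulation (exponential dwell times from the rate
#' matrix), superposed over \code{nChannels} channels, then sampled at the
#' model's sampling rate. Additive Gaussian noise is applied per sample;
#' optional Gaussian low-pass smoothing approximates the recording filter
#' (kernel matched to the -3 dB point of an 8-pole Bessel at
#' \code{filterCutoff}).
#'
#' @param model a \code{\linkS4class{GatingModel}}.
#' @param voltage command potential, mV.
#' @param duration trace length, s (at least 10 sample intervals).
#' @param seed integer RNG seed; identical seeds give identical traces.
#' @param filter apply the low-pass smoothing (default \code{FALSE}).
#' @return a \code{\linkS4class{SimulatedTrace}}.
#' @export
simulateTrace <- function(model, voltage, duration, seed, filter = FALSE) {
  stopifnot(is(model, "GatingModel"))
  validObject(model)
  dt <- 1 / model@sampleRate
  if (duration < 10 * dt)
    stop("duration must span at least 10 sample intervals", call. = FALSE)
  set.seed(as.integer(seed))
  jumps <- if (model@type == "two_state" && model@nChannels == 1L)
    .simulateTwoStateSingle(model, duration)
  else .simulateJumps(model, duration)
  # collapse jumps that do not change the open count
  keep <- c(TRUE, diff(jumps$levels) != 0L)
  times <- jumps$times[keep]
  levels <- jumps$levels[keep]
  nSamples <- floor(duration / dt)
  sampleTimes <- (seq_len(nSamples) - 1L) * dt
  statePath <- levels[findInterval(sampleTimes, times)]
  amp <- model@gamma * (voltage - model@vRev) / 1000
  current <- statePath * amp
  if (model@noiseSd > 0)
    current <- current + stats::rnorm(nSamples, 0, model@noiseSd)
  if (filter && is.finite(model@filterCutoff) && model@filterCutoff > 0) {
    sigma <- sqrt(log(2)) / (2 * pi * model@filterCutoff) / dt  # in samples
    hw <- max(1L, ceiling(4 * sigma))
    kern <- stats::dnorm(seq(-hw, hw), sd = sigma)
    kern <- kern / sum(kern)
    padded <- c(rep(current[1L], hw), current, rep(current[nSamples], hw))
    current <- stats::filter(padded, kern, sides = 2L)[(hw + 1L):(hw + nSamples)]
    current <- as.numeric(current)
  }
  new("SimulatedTrace", dt = dt, samples = current,
      statePath = as.integer(statePath), eventTimes = times,
      eventLevels = as.integer(levels), voltage = voltage,
      unitaryAmplitude = amp, duration = nSamples * dt,
      seed = as.integer(seed))
}

#' IdealizedEvents: dwell sequence of an idealized recording
#'
#' An ordered run of (open-channel level, duration) dwells. Consecutive
#' events always differ in level, and after dead-time filtering every event
#' is at least \code{deadTime} long (a single surviving event may be
#' shorter than the record itself allows).
#'
#' @slot levels integer open-channel count per event.
#' @slot durations event durations, s.
#' @slot deadTime dead time applied, s.
#' @slot totalDuration sum of durations, s.
#' @export
setClass("IdealizedEvents",
  representation(levels = "integer", durations = "numeric",
                 deadTime = "numeric", totalDuration = "numeric"))

setValidity("IdealizedEvents", function(object) {
  if (length(object@levels) != length(object@durations))
    return("levels and durations must have equal length")
  if (length(object@levels) == 0L) return("event list may not be empty")
  if (any(diff(object@levels) == 0L))
    return("consecutive events must differ in level")
  if (abs(sum(object@durations) - object@totalDuration) >
      1e-9 * max(1, object@totalDuration))
    return("durations must sum to totalDuration")
  if (length(object@levels) > 1L &&
      any(object@durations < object@deadTime - 1e-12))
    return("all durations must be >= deadTime after merging")
  TRUE
})

setMethod("show", "IdealizedEvents", function(object) {
  cat(sprintf("IdealizedEvents: %d events over %.4g s (dead time %g us)\n",
              length(object@levels), object@totalDuration,
              object@deadTime * 1e6))
})

#' Events accessor
#' @param x an \code{IdealizedEvents}.
#' @return data.frame with columns \code{level}, \code{duration}.
#' @export
eventTable <- function(x) {
  stopifnot(is(x, "IdealizedEvents"))
  data.frame(level = x@levels, duration = x@durations)
}

# build IdealizedEvents from a level/duration run, applying the dead-time
# rule: events shorter than deadTime are absorbed into the longer
# neighboring event (ties toward the preceding event), repeatedly, shortest
# first.
.makeEvents <- function(levels, durations, deadTime) {
  keep <- durations > 0
  levels <- levels[keep]; durations <- durations[keep]
  # collapse equal adjacent levels
  if (length(levels) > 1L) {
    grp <- cumsum(c(TRUE, diff(levels) != 0L))
    durations <- as.numeric(tapply(durations, grp, sum))
    levels <- levels[!duplicated(grp)]
  }
  total <- sum(durations)
  if (deadTime > 0 && length(levels) > 1L) {
    merged <- merge_dead_time(as.integer(levels), as.numeric(durations),
                              deadTime)
    levels <- merged$levels
    durations <- merged$durations
  }
  new("IdealizedEvents", levels = as.integer(levels),
      durations = as.numeric(durations), deadTime = deadTime,
      totalDuration = total)
}

#' Idealize a current trace by half-amplitude threshold crossing
#'
#' Assigns each sample the open-channel level nearest to
#' \code{current / unitaryAmplitude}, accepting a level transition only when
#' the current crosses \code{(level +/- thresholdFraction)} times the
#' unitary amplitude (hysteresis; multi-channel records are handled by
#' nearest-multiple assignment). Events shorter than \code{deadTime} are
#' merged into the longer neighboring event (ties toward the preceding
#' event).
#'
#' @param trace a \code{\linkS4class{SimulatedTrace}}, or a numeric vector
#'   of currents (then \code{dt} must be given).
#' @param unitaryAmplitude single-open-channel current, pA (sign must match
#'   the trace polarity). Defaults to the trace's own amplitude.
#' @param thresholdFraction crossing threshold as a fraction of the unitary
#'   amplitude (default 0.5, the half-amplitude criterion).
#' @param deadTime shortest resolvable event, s (default 1e-4, i.e. 100 us).
#' @param dt sample interval, s (only when \code{trace} is a plain vector).
#' @return an \code{\linkS4class{IdealizedEvents}}.
#' @export
idealizeTrace <- function(trace, unitaryAmplitude = NULL,
                          thresholdFraction = 0.5, deadTime = 1e-4,
                          dt = NULL) {
  if (is(trace, "SimulatedTrace")) {
    samples <- trace@samples
    dt <- trace@dt
    if (is.null(unitaryAmplitude)) unitaryAmplitude <- trace@unitaryAmplitude
  } else {
    samples <- as.numeric(trace)
    if (is.null(dt)) stop("dt must be supplied for a plain sample vector",
                          call. = FALSE)
    if (is.null(unitaryAmplitude))
      stop("unitaryAmplitude must be supplied for a plain sample vector",
           call. = FALSE)
  }
  if (unitaryAmplitude == 0) stop("unitaryAmplitude may not be 0",
                                  call. = FALSE)
  x <- samples / unitaryAmplitude
  # polarity check: excursions toward negative levels with none toward
  # positive levels mean the amplitude sign does not match the trace
  if (stats::quantile(x, 0.01) < -0.5 && stats::quantile(x, 0.99) < 0.5)
    stop("unitary amplitude sign inconsistent with trace polarity",
         call. = FALSE)
  lev <- hysteresis_levels(x, thresholdFraction)
  r <- rle(lev)
  .makeEvents(r$values, r$lengths * dt, deadTime)
}

#' Exact event path of a simulated trace
#'
#' Builds the dwell sequence directly from the simulator's continuous-time
#' jump record (no sampling quantization); useful as ground truth when
#' assessing the idealization, and for unbiased dwell-time statistics.
#'
#' @param trace a \code{\linkS4class{SimulatedTrace}}.
#' @param deadTime optional dead time to apply, s (default 0).
#' @return an \code{\linkS4class{IdealizedEvents}}.
#' @export
trueEvents <- function(trace, deadTime = 0) {
  stopifnot(is(trace, "SimulatedTrace"))
  times <- trace@eventTimes
  durations <- diff(c(times, trace@duration))
  .makeEvents(trace@eventLevels, durations, deadTime)
}

#' Single-channel statistics from idealized events
#'
#' NPo is the time-averaged open-channel count,
#' \eqn{\sum_k \mathrm{level}_k \, \mathrm{dur}_k / T}. Open and closed
#' dwell means use single-channel semantics: any level >= 1 counts as open.
#' Per-channel Po is reported when the channel count is known.
#'
#' @param events an \code{\linkS4class{IdealizedEvents}}.
#' @param nChannels optional known channel count N.
#' @param unitaryAmplitude optional unitary current, pA (copied through).
#' @param voltage,vRev optional potentials, mV, used to convert the unitary
#'   amplitude into a conductance.
#' @return list with \code{NPo}, \code{mean_open_time_ms},
#'   \code{mean_closed_time_ms}, \code{n_open_events},
#'   \code{n_closed_events}, \code{Po_per_channel} (NA when N unknown),
#'   \code{unitary_amplitude_pA}, \code{unitary_conductance_pS}.
#' @export
channelStats <- function(events, nChannels = NULL, unitaryAmplitude = NA,
                         voltage = NA, vRev = 0) {
  stopifnot(is(events, "IdealizedEvents"))
  lev <- events@levels
  dur <- events@durations
  total <- events@totalDuration
  npo <- sum(lev * dur) / total
  isOpen <- lev >= 1L
  meanOpen <- if (any(isOpen)) mean(dur[isOpen]) * 1000 else NA_real_
  meanClosed <- if (any(!isOpen)) mean(dur[!isOpen]) * 1000 else NA_real_
  gPs <- if (!is.na(unitaryAmplitude) && !is.na(voltage) &&
             voltage != vRev)
    unitaryAmplitude / (voltage - vRev) * 1000 else NA_real_
  list(NPo = npo,
       mean_open_time_ms = meanOpen,
       mean_closed_time_ms = meanClosed,
       n_open_events = sum(isOpen),
       n_closed_events = sum(!isOpen),
       Po_per_channel = if (is.null(nChannels)) NA_real_
                        else npo / nChannels,
       unitary_amplitude_pA = unitaryAmplitude,
       unitary_conductance_pS = gPs)
}

#' Unitary conductance and reversal potential from an i-V relationship
#'
#' Least-squares line through unitary current amplitude versus voltage;
#' the slope (converted to pS) is the unitary conductance and the
#' x-intercept the reversal potential.
#'
#' @param voltage voltages, mV.
#' @param amplitude unitary current amplitudes, pA.
#' @return list with \code{conductance_pS}, \code{reversal_mV}.
#' @export
unitaryIV <- function(voltage, amplitude) {
  if (length(voltage) != length(amplitude) || length(voltage) < 2L)
    stop("need >= 2 (voltage, amplitude) points", call. = FALSE)
  if (length(unique(voltage)) < 2L)
    stop("all voltages identical: cannot fit an i-V line", call. = FALSE)
  fit <- stats::lm(amplitude ~ voltage)
  slope <- unname(coef(fit)[2L])   # pA / mV
  intercept <- unname(coef(fit)[1L])
  list(conductance_pS = slope * 1000, reversal_mV = -intercept / slope)
}

#' Macroscopic whole-cell current from microscopic parameters
#'
#' \eqn{I = N \gamma P_o (V - V_{rev})}: the whole-cell model under which an
#' increase in single-channel open probability maps linearly onto
#' whole-cell current.
#'
#' @param N channel count.
#' @param gamma unitary conductance, pS.
#' @param Po open probability in [0, 1].
#' @param V membrane potential, mV.
#' @param vRev reversal potential, mV.
#' @return current, pA.
#' @export
wholeCellCurrent <- function(N, gamma, Po, V, vRev = 0) {
  if (any(Po < 0 | Po > 1)) stop("Po must lie in [0, 1]", call. = FALSE)
  N * gamma * Po * (V - vRev) / 1000
}

#' Whole-cell fold change implied by an open-probability change
#'
#' At fixed N, gamma and driving force the whole-cell current ratio equals
#' the open-probability ratio.
#'
#' @param poMut,poWt mutant and wild-type open probabilities in [0, 1].
#' @return \code{poMut / poWt}.
#' @export
foldChange <- function(poMut, poWt) {
  if (any(c(poMut, poWt) < 0 | c(poMut, poWt) > 1))
    stop("Po must lie in [0, 1]", call. = FALSE)
  if (poWt == 0) stop("wild-type Po may not be 0", call. = FALSE)
  poMut / poWt
}

#' Fit a single-exponential activation time constant
#'
#' Least-squares fit of \eqn{I(t) = I_\infty + (I_0 - I_\infty)
#' e^{-(t - t_0)/\tau}} to an activating (or deactivating) current trace,
#' as used for time constants of slowly activating whole-cell currents.
#' Initial guesses come from the data range and the 63\% rise time.
#'
#' @param time times, s.
#' @param current currents (any consistent unit).
#' @return list with \code{tau_ms}, \code{amplitude} (\eqn{I_0 - I_\infty})
#'   and \code{offset} (\eqn{I_\infty}).
#' @export
fitActivationTau <- function(time, current) {
  if (length(time) != length(current) || length(time) < 10L)
    stop("need >= 10 (time, current) samples", call. = FALSE)
  t0 <- time[1L]
  i0 <- current[1L]
  iInf <- mean(utils::tail(current, max(3L, length(current) %/% 20L)))
  span <- iInf - i0
  if (abs(span) < 1e-12 * max(1, abs(iInf)) ||
      stats::sd(current) < 1e-12 * max(1, abs(iInf)))
    stop("non-convergence: no activation trend in trace", call. = FALSE)
  frac <- (current - i0) / span
  i63 <- which(frac >= 0.632)[1L]
  tauGuess <- if (!is.na(i63) && i63 > 1L) time[i63] - t0
              else (max(time) - t0) / 3
  tauGuess <- max(tauGuess, (time[2L] - time[1L]))
  tt <- time - t0
  resid <- function(p) p[1L] + (p[2L] - p[1L]) * exp(-tt / p[3L]) - current
  jac <- function(p) {
    e <- exp(-tt / p[3L])
    cbind(1 - e, e, (p[2L] - p[1L]) * e * tt / p[3L]^2)
  }
  fit <- minpack.lm::nls.lm(par = c(iInf, i0, tauGuess), fn = resid,
                            jac = jac,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (fit$info < 1L || fit$info > 4L)
    stop("non-convergence in exponential fit: ", fit$message, call. = FALSE)
  est <- fit$par
  if (!is.finite(est[3L]) || est[3L] <= 0)
    stop("non-convergence: fitted tau is not positive", call. = FALSE)
  list(tau_ms = est[3L] * 1000,
       amplitude = est[2L] - est[1L],
       offset = est[1L])
}
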