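#' Preprocessing configuration for amplitude-contrast reduction
#'
#' Parameters of the three-stage preprocessing that shrinks the amplitude
#' contrast between heavy and weak breathing cycles: a signed entropy
#' transform, a piecewise contrast cut, and a soft amplitude limiter.
#' Defaults are the experimentally chosen constants: `a = 0.4`,
#' `|b| = 0.6`, `c = 1.5`, limiting factor `0.85` with exponent `20`.
#'
#' @param a weakening factor applied to the strong part, `0 < a < 1`.
#' @param b_mag magnitude of the additive offset in the strong branch
#'   (applied with the sign of H), `>= 0`.
#' @param c_enh enhancement factor for the weak part, `>= 1`.
#' @param limit_factor limiting amplitude factor in `[0, 1]` (the soft
#'   limiter's mixing weight).
#' @param limit_power limiter exponent; a positive even integer.
#' @param block_s optional block length in seconds: the reference level
#'   `av` is computed per block instead of over the whole recording.
#'   `NULL` (default) processes the recording as one block.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(a = 0.4, b_mag = 0.6, c_enh = 1.5,
                              limit_factor = 0.85, limit_power = 20,
                              block_s = NULL) {
  if (!(a > 0 && a < 1)) stop("`a` must be in (0, 1)")
  if (b_mag < 0) stop("`b_mag` must be >= 0")
  if (c_enh < 1) stop("`c_enh` must be >= 1")
  if (limit_factor < 0 || limit_factor > 1) stop("`limit_factor` must be in [0, 1]")
  if (limit_power < 2 || limit_power %% 2 != 0) {
    stop("`limit_power` must be an even integer >= 2")
  }
  if (!is.null(block_s) && block_s <= 0) stop("`block_s` must be positive")
  structure(list(a = a, b_mag = b_mag, c_enh = c_enh,
                 limit_factor = limit_factor, limit_power = limit_power,
                 block_s = block_s),
            class = "preprocess_config")
}

new_entropy_signal <- function(values, av, sample_rate, start_time) {
  structure(list(values = values, av = av, sample_rate = sample_rate,
                 start_time = start_time),
            class = "entropy_signal")
}

#' Signed entropy transform of a normalized signal
#'
#' Maps each sample y to `H = -sign(y) * |y| * ln|y|` (zero maps to zero).
#' For `|y| <= 1` this preserves the sign of y while boosting small
#' amplitudes relative to large ones, which is the first step of the
#' amplitude-contrast reduction. The reference level `av` is the mean of
#' `|H|` over the signal.
#'
#' @param signal an [audio_signal()] with samples in `[-1, 1]`
#'   (apply [normalize_amplitude()] first).
#' @return An `entropy_signal`: values `H(t)` on the same time axis, plus
#'   the scalar reference level `av`.
#' @export
entropy_transform <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  y <- signal$samples
  if (length(y) && max(abs(y)) > 1 + 1e-12) {
    stop("samples must lie in [-1, 1]; call normalize_amplitude() first")
  }
  H <- numeric(length(y))
  nz <- y != 0
  H[nz] <- -sign(y[nz]) * abs(y[nz]) * log(abs(y[nz]))
  new_entropy_signal(H, mean(abs(H)), signal$sample_rate, signal$start_time)
}

#' Piecewise contrast cut
#'
#' Weakens samples whose entropy magnitude exceeds the reference level `av`
#' (`a * H + sign(H) * b_mag * av`) and enhances the rest (`c_enh * H`),
#' shrinking the intensity difference between strong and weak breathing
#' cycles. `av` is recomputed on the output.
#'
#' @param H an `entropy_signal` from [entropy_transform()].
#' @param config a [preprocess_config()].
#' @return An `entropy_signal` of cut values.
#' @export
contrast_cut <- function(H, config = preprocess_config()) {
  stopifnot(inherits(H, "entropy_signal"), inherits(config, "preprocess_config"))
  v <- H$values
  av <- H$av
  strong <- abs(v) > av
  out <- v
  out[strong] <- config$a * v[strong] + sign(v[strong]) * config$b_mag * av
  out[!strong] <- config$c_enh * v[!strong]
  new_entropy_signal(out, mean(abs(out)), H$sample_rate, H$start_time)
}

#' Soft amplitude limiter
#'
#' Applies `y_enhance = H * (1 - l + l * |H|^N)` with limiting factor `l`
#' and even power `N`. Fixed points: 0 maps to 0 and 1 maps to 1; values in
#' between are attenuated towards `(1 - l) * H`, flattening residual peaks.
#'
#' @param H_cut an `entropy_signal` (normally from [contrast_cut()]).
#' @param config a [preprocess_config()].
#' @return An [audio_signal()] on the same time axis.
#' @export
amplitude_limit <- function(H_cut, config = preprocess_config()) {
  stopifnot(inherits(H_cut, "entropy_signal"), inherits(config, "preprocess_config"))
  v <- H_cut$values
  out <- v * (1 - config$limit_factor +
                config$limit_factor * abs(v)^config$limit_power)
  audio_signal(out, H_cut$sample_rate, H_cut$start_time)
}

#' Amplitude-contrast reducing preprocessing
#'
#' Composition [amplitude_limit()] o [contrast_cut()] o
#' [entropy_transform()]. Every stage is an odd function of its input
#' sample, so the sign pattern of the output equals that of the input; the
#' RMS ratio between a strong and a weak burst can only shrink. With
#' `config$block_s` set, the recording is processed in consecutive blocks
#' so that the reference level `av` tracks slow level drift.
#'
#' @param signal an [audio_signal()] normalized to `[-1, 1]`.
#' @param config a [preprocess_config()].
#' @return An [audio_signal()] on the same time axis as the input.
#' @export
preprocess <- function(signal, config = preprocess_config()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "preprocess_config"))
  run_block <- function(sig) {
    amplitude_limit(contrast_cut(entropy_transform(sig), config), config)
  }
  if (is.null(config$block_s)) return(run_block(signal))
  n <- length(signal$samples)
  bl <- max(1L, round(config$block_s * signal$sample_rate))
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + bl - 1L)
    blk <- audio_signal(signal$samples[i:j], signal$sample_rate)
    out[i:j] <- run_block(blk)$samples
    i <- j + 1L
  }
  audio_signal(out, signal$sample_rate, signal$start_time)
}
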