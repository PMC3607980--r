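#' Ependymal CBF validation measurements
#'
#' A small bundled table of ependymal ciliary beat frequency measurements
#' (Hz) from a validation experiment in which brain-slice ependymal cilia
#' were slowed by the pneumococcal toxin pneumolysin. The same regions were
#' measured by the automated FFT pipeline (`ciliafa_hz`) and by two
#' observers using direct counting of beat cycles during slow-motion
#' playback (`direct_obs1_hz`, `direct_obs2_hz`, plus a repeat count by
#' observer 1), before (`time_min = 0`) and 5 minutes after toxin exposure.
#'
#' @return A data frame with columns `time_min`, `ciliafa_hz`,
#'   `direct_obs1_hz`, `direct_obs2_hz`, `direct_obs1_second_hz`.
#' @examples
#' d <- ependymal_cbf_table()
#' mean(d$ciliafa_hz[d$time_min == 5])
#' @export
ependymal_cbf_table <- function() {
  utils::read.csv(system.file("extdata", "ependymal_pneumolysin_cbf.csv",
                              package = "ciliafreq"))
}
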