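Package: cmwbreath
Title: Sleep Respiratory Rate and Apnea Event Detection from Breathing
    Sounds via Characteristic Moment Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects the sleep respiratory rate (RR) and extracts
    apnea/hypopnea events from breathing-sound audio recordings.  The
    signal is first passed through an amplitude-contrast reduction step
    (a signed entropy transform, a piecewise contrast cut and a soft
    amplitude limiter), then summarised by a time characteristic
    waveform (TCW, a sliding-window variance computed in O(n) with
    prefix sums) and a characteristic moment waveform (CMW, the local
    second moment of the TCW).  Breath-cycle segment points are placed
    at TCW minima validated by prominent CMW maxima; per-minute cycle
    counts give the RR series, from which a stable-rate threshold flags
    apnea (pauses of 10 s or more) and hypopnea events and computes the
    apnea-hypopnea index (AHI).  Includes a synthetic breathing-sound
    simulator with ground-truth annotations, an evaluation routine for
    boundary-detection success rates, WAV input/output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
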