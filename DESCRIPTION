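Package: pavda
Title: Analysis of Pavlovian Conditioning Sessions with Midbrain Dopamine Recordings
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse combined behavioural and extracellular recording
    sessions from Pavlovian conditioning experiments in which peripheral visual
    cues predict rewards of different sizes. Provides a documented on-disk
    session bundle (trial table, spike trains, spike waveforms, lick events,
    saccade psychophysics), putative dopamine-neuron classification from
    baseline rate and trough-to-peak spike width, peristimulus time histograms
    and window firing-rate statistics, response-latency estimation against a
    baseline mean + k*SD criterion, sliding exact sign tests for the onset of
    reward-value discrimination across a neuron population, conditioned-licking
    quantification with the standard paired and unpaired tests, reversible
    inactivation contrasts, and d-prime based contrast-threshold mapping of
    visual-field deficits. A synthetic-session generator with known ground
    truth (inhomogeneous Poisson spike trains, anticipatory lick point
    processes, contrast-graded saccade trials) supports parameter-recovery
    testing of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
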