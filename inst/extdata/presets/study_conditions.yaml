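# Published study conditions of the iPSC-derived ASD vs control
# calcium-imaging experiments, re-expressed as generative parameters.
# mu_peak: grand-mean maximum receptor-mediated fold response (all cells,
#   responders and non-responders pooled).
# mu_ttp: mean time from stimulus delivery to the RMR maximum, seconds.
# responder_frac: reported percent of cells doubling their response / 100
#   (1.0 where the study describes homogeneous responses and reports no
#   doubling percentage).
# mu_iono_peak / mu_iono_ttp: ionomycin maximum fold and time-to-peak.
#   The 1-week KCl ionomycin statistics were not reported (no group
#   difference); 2.85 fold at 40 s is used for both groups as typical of the
#   neighbouring conditions. The iPSC-stage ionomycin time-to-peak was
#   likewise not reported; 50 s is used for both groups.
# Unlisted keys take the CohortPreset() defaults.

- {group: ASD,     stage: iPSC,    stimulus: ATP,  mu_peak: 4.23, mu_ttp: 82.59, responder_frac: 1.0,    mu_iono_peak: 3.60, mu_iono_ttp: 50}
- {group: control, stage: iPSC,    stimulus: ATP,  mu_peak: 3.71, mu_ttp: 49.87, responder_frac: 1.0,    mu_iono_peak: 3.89, mu_iono_ttp: 50}

- {group: ASD,     stage: Diff1wk, stimulus: KCl,  mu_peak: 2.55, mu_ttp: 15.57, responder_frac: 0.5737, mu_iono_peak: 2.85, mu_iono_ttp: 40}
- {group: control, stage: Diff1wk, stimulus: KCl,  mu_peak: 2.20, mu_ttp: 36.88, responder_frac: 0.4230, mu_iono_peak: 2.85, mu_iono_ttp: 40}
- {group: ASD,     stage: Diff1wk, stimulus: ATP,  mu_peak: 1.58, mu_ttp: 57.00, responder_frac: 0.1363, mu_iono_peak: 2.73, mu_iono_ttp: 81.69}
- {group: control, stage: Diff1wk, stimulus: ATP,  mu_peak: 2.74, mu_ttp: 27.62, responder_frac: 0.85,   mu_iono_peak: 2.97, mu_iono_ttp: 37.85}

- {group: ASD,     stage: Diff4wk, stimulus: KCl,  mu_peak: 3.30, mu_ttp: 14.38, responder_frac: 0.8571, mu_iono_peak: 3.28, mu_iono_ttp: 36.16}
- {group: control, stage: Diff4wk, stimulus: KCl,  mu_peak: 2.75, mu_ttp: 20.97, responder_frac: 0.7522, mu_iono_peak: 2.89, mu_iono_ttp: 51.64}
- {group: ASD,     stage: Diff4wk, stimulus: ATP,  mu_peak: 2.35, mu_ttp: 38.00, responder_frac: 0.5819, mu_iono_peak: 2.97, mu_iono_ttp: 45.35}
- {group: control, stage: Diff4wk, stimulus: ATP,  mu_peak: 2.88, mu_ttp: 27.53, responder_frac: 0.9078, mu_iono_peak: 3.60, mu_iono_ttp: 36.27}
- {group: ASD,     stage: Diff4wk, stimulus: DHPG, mu_peak: 2.68, mu_ttp: 14.07, responder_frac: 0.5957, mu_iono_peak: 3.22, mu_iono_ttp: 33.31}
- {group: control, stage: Diff4wk, stimulus: DHPG, mu_peak: 2.14, mu_ttp: 25.86, responder_frac: 0.5113, mu_iono_peak: 2.81, mu_iono_ttp: 53.15}
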