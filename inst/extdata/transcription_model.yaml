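# Delayed stochastic model of single-gene transcription.
# Initiation occupies the promoter for a constant 40 s (open complex
# formation); the finished transcript appears after a Gaussian completion
# delay; transcripts degrade with a 10 min mean lifetime.
species:
  Pro: 1
  RNA: 0
reactions:
  - name: initiation
    reactants: {Pro: 1}
    delayed:
      - species: Pro
        count: 1
        delay: {mean: 40, sd: 0, kind: constant}
      - species: RNA
        count: 1
        delay: {mean: 102, sd: 14, kind: gaussian}
    rate: 0.05
  - name: degradation
    reactants: {RNA: 1}
    rate: 0.0016666666666666668
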