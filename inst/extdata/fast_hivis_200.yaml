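wave_speed: 0.008
preset: HIVIS
volume: 0.0002
resolution: 2.0
cadence: 0.25
settle_time: 1.5
duration: ~
through_segment: ~
amp_contract: ~
amp_relax: ~
jitter: 0.0
seed: 1
constriction_radius_fraction: 0.4
c0: 0.1
gravity: 0.0
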