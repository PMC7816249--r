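# Demo configuration for the synthetic study system: 12 simulated fall
# migrations on a 60 x 60 km landscape, full scenario testing and road
# impact assessment.  All other keys take package defaults (availability
# ratio 20, stretch 1-1000, 8-neighbour solves, 20-km buffers, 10 folds,
# 500 bootstrap draws).
seed: 7
extent: [0, 60, 0, 60]
cellSize: 1
nAnimals: 12
season: fall
trueScenario: r3
trueAlpha: 30
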