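log2fcMin: 0.5
pMax: 0.05
fdrMode: report
fdrMax: 0.05
corrRequireNegative: yes
corrPMax: 0.05
corrRequireOpposite: yes
mclInflation: 2.0
mclExpansion: 2.0
mclPruneMin: 1.00000000000000008e-05
mclMaxIter: 100.0
mclTol: 1.00000000000000002e-08
svmCost: 1.0
svmGamma: .na.real
scaleMode: zscore
cvFolds: 5.0
cvRepeats: 5.0
topKEdges: 2.0
seed: 20.0
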