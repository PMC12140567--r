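region	hemisphere	lobe
lh-bankssts	lh	temporal
lh-caudalanteriorcingulate	lh	cingulate
lh-caudalmiddlefrontal	lh	frontal
lh-cuneus	lh	occipital
lh-entorhinal	lh	temporal
lh-fusiform	lh	temporal
lh-inferiorparietal	lh	parietal
lh-inferiortemporal	lh	temporal
lh-isthmuscingulate	lh	cingulate
lh-lateraloccipital	lh	occipital
lh-lateralorbitofrontal	lh	frontal
lh-lingual	lh	occipital
lh-medialorbitofrontal	lh	frontal
lh-middletemporal	lh	temporal
lh-parahippocampal	lh	temporal
lh-paracentral	lh	frontal
lh-parsopercularis	lh	frontal
lh-parsorbitalis	lh	frontal
lh-parstriangularis	lh	frontal
lh-pericalcarine	lh	occipital
lh-postcentral	lh	parietal
lh-posteriorcingulate	lh	cingulate
lh-precentral	lh	frontal
lh-precuneus	lh	parietal
lh-rostralanteriorcingulate	lh	cingulate
lh-rostralmiddlefrontal	lh	frontal
lh-superiorfrontal	lh	frontal
lh-superiorparietal	lh	parietal
lh-superiortemporal	lh	temporal
lh-supramarginal	lh	parietal
lh-frontalpole	lh	frontal
lh-temporalpole	lh	temporal
lh-transversetemporal	lh	temporal
lh-insula	lh	insula
rh-bankssts	rh	temporal
rh-caudalanteriorcingulate	rh	cingulate
rh-caudalmiddlefrontal	rh	frontal
rh-cuneus	rh	occipital
rh-entorhinal	rh	temporal
rh-fusiform	rh	temporal
rh-inferiorparietal	rh	parietal
rh-inferiortemporal	rh	temporal
rh-isthmuscingulate	rh	cingulate
rh-lateraloccipital	rh	occipital
rh-lateralorbitofrontal	rh	frontal
rh-lingual	rh	occipital
rh-medialorbitofrontal	rh	frontal
rh-middletemporal	rh	temporal
rh-parahippocampal	rh	temporal
rh-paracentral	rh	frontal
rh-parsopercularis	rh	frontal
rh-parsorbitalis	rh	frontal
rh-parstriangularis	rh	frontal
rh-pericalcarine	rh	occipital
rh-postcentral	rh	parietal
rh-posteriorcingulate	rh	cingulate
rh-precentral	rh	frontal
rh-precuneus	rh	parietal
rh-rostralanteriorcingulate	rh	cingulate
rh-rostralmiddlefrontal	rh	frontal
rh-superiorfrontal	rh	frontal
rh-superiorparietal	rh	parietal
rh-superiortemporal	rh	temporal
rh-supramarginal	rh	parietal
rh-frontalpole	rh	frontal
rh-temporalpole	rh	temporal
rh-transversetemporal	rh	temporal
rh-insula	rh	insula
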