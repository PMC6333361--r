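# sos_synthetic

A SYNTHETIC parameterization on the published structure of the Strait of
Sicily food-web model: 72 functional-group codes, long names and domain
labels, 18 fleet segments, 3 detritus pools, a 70% diet import for
bluefin tuna (THU), an immigration term for swordfish (XIP), and biomass
estimated instead of ecotrophic efficiency for BO, EUP and MB.

All numeric parameters (biomasses, rates, diet fractions, catches) are
synthetic values from trophicweb's balanced-web generator
(data-raw/sos_synthetic.R, seed 42). They are NOT the published values;
use this model as a realistic-sized test bed only.
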