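# Published precision-movement miss counts: group means and SEMs of per-animal
# mean misses per trial, for control versus ERR2/3 conditional-knockout (cko)
# mice crossing horizontal beams of decreasing width (30/25/20 mm) and a
# horizontal ladder. N = animals per group; 4-5 trials per animal.
#
# columns: condition group mean sem n_animals
beam_30mm  control  1.00  0.175  4
beam_30mm  err23cko 18.0  1.75   4
beam_25mm  control  1.00  0.125  4
beam_25mm  err23cko 55.0  2.20   4
beam_20mm  control  1.00  0.125  4
beam_20mm  err23cko 79.0  3.49   4
ladder     control  1.00  0.55   5
ladder     err23cko 7.12  2.06   5
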