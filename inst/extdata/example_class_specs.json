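[{"name":"plum","n":50,"size_mean":180,"size_sd":12,"aspect_mean":0.72,"aspect_sd":0.04,"squareness_mean":2.3,"squareness_sd":0.15,"boundary_noise":0.02},{"name":"watermelon","n":50,"size_mean":75,"size_sd":6,"aspect_mean":0.62,"aspect_sd":0.04,"squareness_mean":2,"squareness_sd":0.1,"boundary_noise":0.015},{"name":"grape","n":50,"size_mean":45,"size_sd":4,"aspect_mean":0.55,"aspect_sd":0.05,"squareness_mean":1.7,"squareness_sd":0.1,"boundary_noise":0.03}]
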