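scenario,longitude,latitude,reportedShiftM
current,113.81,34.62,0
ssp126_2090s,114.18,34.39,42220
ssp245_2050s,113.70,33.91,NA
ssp245_2090s,114.30,34.31,72318
ssp585_2090s,113.81,34.19,45257
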