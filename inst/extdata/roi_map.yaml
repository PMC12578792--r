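# Channel -> region-of-interest map for the 44-channel bilateral array
# (illustrative layout: left device channels 1-22, right device 23-44).
# MFG = medial frontal gyrus (2 channels per hemisphere), STS = superior
# temporal gyrus/sulcus (6), TPJ = temporo-parietal junction (3: two angular,
# one supramarginal). Channels outside the six ROIs are measured but not
# aggregated.
lMFG: [1, 2]
lSTS: [3, 4, 5, 6, 7, 8]
lTPJ: [9, 10, 11]
rMFG: [23, 24]
rSTS: [25, 26, 27, 28, 29, 30]
rTPJ: [31, 32, 33]
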