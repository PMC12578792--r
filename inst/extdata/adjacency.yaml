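# Channel adjacency (edge list) for the 44-channel array. Two devices of 22
# channels each; no edges cross the midline. The layout is illustrative (the
# physical optode geometry of any given cap should be supplied by the user):
# a rostro-caudal chain per hemisphere with cross-links inside each region.
n_channels: 44
edges:
  - [1, 2]
  - [2, 3]
  - [3, 4]
  - [4, 5]
  - [5, 6]
  - [6, 7]
  - [7, 8]
  - [8, 9]
  - [9, 10]
  - [10, 11]
  - [11, 12]
  - [12, 13]
  - [13, 14]
  - [14, 15]
  - [15, 16]
  - [16, 17]
  - [17, 18]
  - [18, 19]
  - [19, 20]
  - [20, 21]
  - [21, 22]
  - [3, 5]
  - [4, 6]
  - [6, 8]
  - [9, 11]
  - [13, 15]
  - [16, 18]
  - [23, 24]
  - [24, 25]
  - [25, 26]
  - [26, 27]
  - [27, 28]
  - [28, 29]
  - [29, 30]
  - [30, 31]
  - [31, 32]
  - [32, 33]
  - [33, 34]
  - [34, 35]
  - [35, 36]
  - [36, 37]
  - [37, 38]
  - [38, 39]
  - [39, 40]
  - [40, 41]
  - [41, 42]
  - [42, 43]
  - [43, 44]
  - [25, 27]
  - [26, 28]
  - [28, 30]
  - [31, 33]
  - [35, 37]
  - [38, 40]
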