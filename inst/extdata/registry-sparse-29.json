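{
  "name": "sparse-29",
  "n_landmarks": 68,
  "midline_indices": [0, 1, 2, 3, 4, 5],
  "pairs": [
    {
      "left": 10,
      "right": 11,
      "region": "other"
    },
    {
      "left": 12,
      "right": 13,
      "region": "other"
    },
    {
      "left": 14,
      "right": 15,
      "region": "other"
    },
    {
      "left": 16,
      "right": 17,
      "region": "other"
    },
    {
      "left": 18,
      "right": 19,
      "region": "other"
    },
    {
      "left": 20,
      "right": 21,
      "region": "other"
    },
    {
      "left": 22,
      "right": 23,
      "region": "other"
    },
    {
      "left": 24,
      "right": 25,
      "region": "other"
    },
    {
      "left": 26,
      "right": 27,
      "region": "eye"
    },
    {
      "left": 28,
      "right": 29,
      "region": "eye"
    },
    {
      "left": 30,
      "right": 31,
      "region": "eye"
    },
    {
      "left": 32,
      "right": 33,
      "region": "eye"
    },
    {
      "left": 34,
      "right": 35,
      "region": "eye"
    },
    {
      "left": 36,
      "right": 37,
      "region": "eye"
    },
    {
      "left": 38,
      "right": 39,
      "region": "eye"
    },
    {
      "left": 40,
      "right": 41,
      "region": "eye"
    },
    {
      "left": 42,
      "right": 43,
      "region": "nose"
    },
    {
      "left": 44,
      "right": 45,
      "region": "nose"
    },
    {
      "left": 46,
      "right": 47,
      "region": "nose"
    },
    {
      "left": 48,
      "right": 49,
      "region": "nose"
    },
    {
      "left": 50,
      "right": 51,
      "region": "mouth"
    },
    {
      "left": 52,
      "right": 53,
      "region": "mouth"
    },
    {
      "left": 54,
      "right": 55,
      "region": "mouth"
    },
    {
      "left": 56,
      "right": 57,
      "region": "mouth"
    },
    {
      "left": 58,
      "right": 59,
      "region": "mouth"
    },
    {
      "left": 60,
      "right": 61,
      "region": "mouth"
    },
    {
      "left": 62,
      "right": 63,
      "region": "mouth"
    },
    {
      "left": 64,
      "right": 65,
      "region": "mouth"
    },
    {
      "left": 66,
      "right": 67,
      "region": "mouth"
    }
  ],
  "subsets": {
    "21": [9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29]
  }
}
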