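{
  "name": "sparse-21",
  "n_landmarks": 68,
  "midline_indices": [0, 1, 2, 3, 4, 5],
  "pairs": [
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
  "subsets": []
}
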