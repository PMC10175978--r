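{
  "generics": [
    {
      "drug": "diazepam",
      "half_life_class": "long_acting"
    },
    {
      "drug": "nitrazepam",
      "half_life_class": "long_acting"
    },
    {
      "drug": "clonazepam",
      "half_life_class": "long_acting"
    },
    {
      "drug": "clobazam",
      "half_life_class": "long_acting"
    },
    {
      "drug": "flunitrazepam",
      "half_life_class": "long_acting"
    },
    {
      "drug": "temazepam",
      "half_life_class": "short_intermediate"
    },
    {
      "drug": "oxazepam",
      "half_life_class": "short_intermediate"
    },
    {
      "drug": "lorazepam",
      "half_life_class": "short_intermediate"
    },
    {
      "drug": "bromazepam",
      "half_life_class": "short_intermediate"
    },
    {
      "drug": "alprazolam",
      "half_life_class": "short_intermediate"
    },
    {
      "drug": "midazolam",
      "half_life_class": "short_intermediate"
    },
    {
      "drug": "zolpidem",
      "half_life_class": "short_intermediate"
    },
    {
      "drug": "zopiclone",
      "half_life_class": "short_intermediate"
    }
  ],
  "synonyms": {
    "valium": "diazepam",
    "antenex": "diazepam",
    "ducene": "diazepam",
    "mogadon": "nitrazepam",
    "alodorm": "nitrazepam",
    "rivotril": "clonazepam",
    "paxam": "clonazepam",
    "frisium": "clobazam",
    "hypnodorm": "flunitrazepam",
    "normison": "temazepam",
    "temaze": "temazepam",
    "serepax": "oxazepam",
    "murelax": "oxazepam",
    "alepam": "oxazepam",
    "ativan": "lorazepam",
    "lexotan": "bromazepam",
    "xanax": "alprazolam",
    "kalma": "alprazolam",
    "alprax": "alprazolam",
    "hypnovel": "midazolam",
    "stilnox": "zolpidem",
    "dormizol": "zolpidem",
    "imovane": "zopiclone",
    "imrest": "zopiclone"
  }
}
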