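[
  {"position": 18,  "wild_type": "Y", "substitutions": "H",     "phenotype": "XP/TTD", "annotated_class": "B"},
  {"position": 47,  "wild_type": "G", "substitutions": "R",     "phenotype": "XP/CS",  "annotated_class": "C"},
  {"position": 76,  "wild_type": "T", "substitutions": "A",     "phenotype": "XP",     "annotated_class": "A"},
  {"position": 112, "wild_type": "R", "substitutions": "H,C",   "phenotype": "XP/TTD", "annotated_class": "A"},
  {"position": 234, "wild_type": "D", "substitutions": "N",     "phenotype": "XP",     "annotated_class": "B"},
  {"position": 461, "wild_type": "L", "substitutions": "V",     "phenotype": "XP/CS",  "annotated_class": "B"},
  {"position": 511, "wild_type": "R", "substitutions": "Q",     "phenotype": "XP",     "annotated_class": "A"},
  {"position": 541, "wild_type": "S", "substitutions": "R",     "phenotype": "XP",     "annotated_class": "A"},
  {"position": 542, "wild_type": "Y", "substitutions": "C",     "phenotype": "XP",     "annotated_class": "A"},
  {"position": 601, "wild_type": "R", "substitutions": "L,W",   "phenotype": "XP",     "annotated_class": "A"},
  {"position": 602, "wild_type": "G", "substitutions": "D",     "phenotype": "XP/CS",  "annotated_class": "C"},
  {"position": 666, "wild_type": "R", "substitutions": "W",     "phenotype": "XP/CS",  "annotated_class": "B"},
  {"position": 681, "wild_type": "D", "substitutions": "G,N,H", "phenotype": "XP",     "annotated_class": "A"},
  {"position": 683, "wild_type": "R", "substitutions": "W,Q",   "phenotype": "XP",     "annotated_class": "A"}
]
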