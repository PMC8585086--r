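[
  {"instrument": "EQ5D", "item": "EQ5D_Mobility", "label": "EQ-5D_Mobility", "min": 1, "max": 5, "subscale": null},
  {"instrument": "EQ5D", "item": "EQ5D_SelfCare", "label": "EQ-5D_Self care", "min": 1, "max": 5, "subscale": null},
  {"instrument": "EQ5D", "item": "EQ5D_UsualActivities", "label": "EQ-5D_Usual activities", "min": 1, "max": 5, "subscale": null},
  {"instrument": "EQ5D", "item": "EQ5D_AnxietyDepression", "label": "EQ-5D_Anxiety/Depression", "min": 1, "max": 5, "subscale": null},
  {"instrument": "EQ5D", "item": "EQ5D_PainDiscomfort", "label": "EQ-5D_Pain/Discomfort", "min": 1, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_PainIntensity", "label": "ODI_Pain intensity", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_PersonalCare", "label": "ODI_Personal care", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_Lifting", "label": "ODI_Lifting", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_Walking", "label": "ODI_Walking", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_Sitting", "label": "ODI_Sitting", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_Standing", "label": "ODI_Standing", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_Sleeping", "label": "ODI_Sleeping", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_SexLife", "label": "ODI_Sex life", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_SocialLife", "label": "ODI_Social life", "min": 0, "max": 5, "subscale": null},
  {"instrument": "ODI", "item": "ODI_Travelling", "label": "ODI_Travelling", "min": 0, "max": 5, "subscale": null},
  {"instrument": "HADS", "item": "HAD_Tense", "label": "HAD_Feeling tense or 'wound up'", "min": 0, "max": 3, "subscale": "anxiety"},
  {"instrument": "HADS", "item": "HAD_Enjoy", "label": "HAD_Enjoying things you used to enjoy", "min": 0, "max": 3, "subscale": "depression"},
  {"instrument": "HADS", "item": "HAD_Awful", "label": "HAD_Feeling that something awful is about to happen", "min": 0, "max": 3, "subscale": "anxiety"},
  {"instrument": "HADS", "item": "HAD_Laugh", "label": "HAD_Laughing and seeing the good side of things", "min": 0, "max": 3, "subscale": "depression"},
  {"instrument": "HADS", "item": "HAD_Worry", "label": "HAD_Worrying thoughts going through your mind", "min": 0, "max": 3, "subscale": "anxiety"},
  {"instrument": "HADS", "item": "HAD_Cheerful", "label": "HAD_Feeling cheerful", "min": 0, "max": 3, "subscale": "depression"},
  {"instrument": "HADS", "item": "HAD_Relaxed", "label": "HAD_Can sit at ease and feel relaxed", "min": 0, "max": 3, "subscale": "anxiety"},
  {"instrument": "HADS", "item": "HAD_SlowedDown", "label": "HAD_Feeling slowed down", "min": 0, "max": 3, "subscale": "depression"},
  {"instrument": "HADS", "item": "HAD_Butterflies", "label": "HAD_Frightened feeling like 'butterflies' in the stomach", "min": 0, "max": 3, "subscale": "anxiety"},
  {"instrument": "HADS", "item": "HAD_Appearance", "label": "HAD_Lost interest in appearance", "min": 0, "max": 3, "subscale": "depression"},
  {"instrument": "HADS", "item": "HAD_Restless", "label": "HAD_Restless as if on the move", "min": 0, "max": 3, "subscale": "anxiety"},
  {"instrument": "HADS", "item": "HAD_LookForward", "label": "HAD_Looking forward with enjoyment to things", "min": 0, "max": 3, "subscale": "depression"},
  {"instrument": "HADS", "item": "HAD_Panic", "label": "HAD_Sudden feeling of panic", "min": 0, "max": 3, "subscale": "anxiety"},
  {"instrument": "HADS", "item": "HAD_Book", "label": "HAD_Enjoying a good book or radio/TV program", "min": 0, "max": 3, "subscale": "depression"}
]
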