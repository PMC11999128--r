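{
  "skeletons": [
    "{age} YEAR OLD PATIENT WITH {conditions} ON HANDLING WITH {drugs}. {adherence} {recommendations} CONTROL IN 3 MONTHS",
    "PACIENTE DE {age} ANOS CON {conditions} EN MANEJO CON {drugs}. {adherence} {recommendations}"
  ],
  "empty_conditions": ["DM TYPE II", "DM TIPO II"],
  "empty_drugs": ["NON PHARMACOLOGICAL MANAGEMENT ONLY", "MANEJO HIGIENICO DIETETICO UNICAMENTE"],
  "adherence": {
    "compliant": [
      "BUENA ADHERENCIA AL TRATAMIENTO.",
      "GOOD ADHERENCE TO TREATMENT REPORTED."
    ],
    "non_compliant": [
      "NO ADHERENCIA AL TRATAMIENTO FARMACOLOGICO.",
      "SPECIAL EMPHASIS ON ADHERING TO THE PHARMACOLOGICAL TREATMENT.",
      "MALA ADHERENCIA AL TRATAMIENTO."
    ]
  },
  "recommendations": {
    "nutrition": ["SE RECOMIENDA DIETA SALUDABLE.", "RECOMMEND HEALTHY DIET."],
    "physical": ["SE RECOMIENDA ACTIVIDAD FISICA.", "RECOMMEND PHYSICAL ACTIVITY."],
    "alcohol": ["RECOMIENDA SUSPENDER ALCOHOL.", "ALCOHOL CESSATION ADVISED."],
    "tobacco": ["RECOMIENDA SUSPENDER TABACO.", "TOBACCO CESSATION ADVISED."]
  },
  "distractors": ["ASA 100X1", "SIGNOS VITALES ESTABLES", "PRN", "FOLLOW UP LABS PENDING", "SE EXPLICAN SIGNOS DE ALARMA"]
}
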