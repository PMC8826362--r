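scale,rho_M0,rho_M12,sig_M0,sig_M12
physical_functioning,0.48,0.53,***,***
role_functioning,0.50,0.52,***,***
social_functioning,0.45,0.45,***,***
emotional_functioning,0.45,0.52,***,***
cognitive_functioning,0.38,0.46,***,***
fatigue,0.55,0.58,***,***
insomnia,0.33,0.33,***,***
pain,0.34,0.54,***,***
nausea_vomiting,0.26,0.30,***,***
dyspnea,0.23,0.25,***,***
appetite_loss,0.21,0.21,***,***
constipation,0.14,0.16,*,**
diarrhea,0.07,0.19,,***
financial_difficulties,0.28,0.34,***,***
body_image,0.43,0.42,***,***
sexual_functioning,0.21,0.31,***,***
sexual_enjoyment,0.25,0.33,***,***
future_perspective,0.34,0.48,***,***
systemic_therapy_side_effects,0.35,0.47,***,***
breast_symptoms,0.27,0.26,***,***
arm_symptoms,0.28,0.39,***,***
upset_by_hair_loss,0.16,0.27,,***
depression,0.52,0.56,***,***
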