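column,type,unit,required,description
id,character,,TRUE,Opaque participant identifier; unique within a visit
visit,enum:pre|post,,TRUE,Visit label; pre = baseline; post = after the 3-month intervention
sex,enum:male|female,,TRUE,Biological sex used by the sex-specific scoring equations and cutoffs
age,numeric,years,TRUE,Chronological age at baseline; eligibility requires >= 20
med_lipid,logical,,FALSE,Taking lipid-lowering medication (default FALSE when absent)
med_bp,logical,,FALSE,Taking antihypertensive medication (default FALSE when absent)
med_glucose,logical,,FALSE,Taking antidiabetic medication (default FALSE when absent)
height,numeric,cm,TRUE,Standing height
weight,numeric,kg,TRUE,Body weight
wc,numeric,cm,TRUE,Waist circumference
sbp,numeric,mmHg,TRUE,Systolic blood pressure
dbp,numeric,mmHg,TRUE,Diastolic blood pressure; must be below sbp
fbs,numeric,mg/dL,TRUE,Fasting blood sugar (>= 8 h fast)
tg,numeric,mg/dL,TRUE,Triglycerides
hdl,numeric,mg/dL,TRUE,High-density lipoprotein cholesterol
exercise_per_week,numeric,count/week,TRUE,Self-reported exercise sessions per week
smoking,enum:nonsmoker|current_smoker,,TRUE,Smoking status
drinking,enum:nondrinker|current_drinker,,TRUE,Drinking status
drink_freq_per_week,numeric,count/week,TRUE,Drinking occasions per week; 0 for nondrinkers
drink_amount_ml,numeric,mL/occasion,TRUE,Alcoholic beverage volume per occasion
alcohol_content_pct,numeric,percent,TRUE,Alcohol content by volume as a number in [0; 100]
sleep_hours,numeric,hours,TRUE,Typical nightly sleep duration; open interval (0; 24)
stress,integer,Likert 1-5,TRUE,Subjective stress; 1 very low to 5 very high
diet,enum:good|bad,,TRUE,Dietary-habit classification
steps_per_day,numeric,steps/day,FALSE,Mean daily step count over the visit's month window; NA if no wear
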