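# Theme -> research-priority category assignments for the seed lexicon's
# canonical themes (curated data; extend alongside the lexicon). Themes not
# listed here fall back to "Other".
theme	category
HIV	Infectious disease and infections
hepatitis C	Infectious disease and infections
hepatitis B	Infectious disease and infections
hepatitis	Infectious disease and infections
tuberculosis	Infectious disease and infections
sexually transmissible infection	Infectious disease and infections
sexually transmissible disease	Infectious disease and infections
COVID-19	Infectious disease and infections
chlamydia	Infectious disease and infections
malaria	Infectious disease and infections
rubella	Infectious disease and infections
norovirus	Infectious disease and infections
mental illness	Mental health
depression	Mental health
antisocial personality disorder	Mental health
posttraumatic stress disorder	Mental health
attention-deficit/hyperactivity disorder	Mental health
psychopathology	Mental health
psychopathy	Mental health
depressive symptom	Mental health
anxiety	Mental health
schizophrenia	Mental health
psychosis	Mental health
substance use	Alcohol and other drug use
alcohol use	Alcohol and other drug use
cannabis	Alcohol and other drug use
cocaine	Alcohol and other drug use
cocaine abuse	Alcohol and other drug use
adolescent substance use	Alcohol and other drug use
intravenous drug	Alcohol and other drug use
opioids	Alcohol and other drug use
nicotine	Alcohol and other drug use
nicotine addiction	Alcohol and other drug use
alcohol-related harm	Alcohol and other drug use
heroin	Alcohol and other drug use
treatment	Health care service
screening program	Health care service
treatment completion	Health care service
school performance	Education (from health to vocational)
academic difficulties	Education (from health to vocational)
maternal connectedness	Women's and maternal health
motherhood	Women's and maternal health
stable home environment	Social determinants of health
childhood sexual abuse	Social determinants of health
school connectedness	Social determinants of health
bullying	Social determinants of health
nutritional improvements	Nutrition
food supplements	Nutrition
learning disability	Cognitive and intellectual disability
intellectual disability	Cognitive and intellectual disability
sanctions	Justice system
law	Justice system
adjudication	Justice system
mortality	Biomedical related
age	Biomedical related
sex	Biomedical related
gender	Biomedical related
injury	Biomedical related
severe injury	Biomedical related
spinal cord injury	Biomedical related
youth	Biomedical related
5httplr	Biomedical related
crime	Offense related
recidivism	Offense related
rearrests	Offense related
offense	Offense related
homicide	Offense related
sexual homicide	Offense related
arson	Offense related
criminality	Offense related
delinquency	Juveniles
adolescent delinquency	Juveniles
offspring disinhibited behavior	Juveniles
violence	Behavior
aggressive behaviour	Behavior
acculturation	Behavior
male-male sex	Behavior
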