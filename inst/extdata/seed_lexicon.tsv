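# Seed theme dictionary: surface terms, canonical theme labels and
# research-priority categories. The working dictionary behind the published
# corpus figures (~2500 terms) is unpublished; this seed covers the themes,
# synonyms, acronyms and category assignments that are explicitly documented,
# and is meant to be extended or replaced by the user (see load_lexicon()).
# An empty category resolves to "Other".
surface	canonical	category
HIV	HIV	Infectious disease and infections
AIDS	HIV	Infectious disease and infections
human immunodeficiency virus	HIV	Infectious disease and infections
hepatitis C	hepatitis C	Infectious disease and infections
hepatitis C virus	hepatitis C	Infectious disease and infections
HPC	hepatitis C	Infectious disease and infections
HCV	hepatitis C	Infectious disease and infections
hepatitis B	hepatitis B	Infectious disease and infections
HBV	hepatitis B	Infectious disease and infections
hepatitis	hepatitis	Infectious disease and infections
tuberculosis	tuberculosis	Infectious disease and infections
TB	tuberculosis	Infectious disease and infections
sexually transmissible infection	sexually transmissible infection	Infectious disease and infections
sexually transmitted infection	sexually transmissible infection	Infectious disease and infections
STI	sexually transmissible infection	Infectious disease and infections
sexually transmissible disease	sexually transmissible disease	Infectious disease and infections
sexually transmitted disease	sexually transmissible disease	Infectious disease and infections
STD	sexually transmissible disease	Infectious disease and infections
COVID-19	COVID-19	Infectious disease and infections
coronavirus disease 2019	COVID-19	Infectious disease and infections
chlamydia	chlamydia	Infectious disease and infections
malaria	malaria	Infectious disease and infections
rubella	rubella	Infectious disease and infections
norovirus	norovirus	Infectious disease and infections
mental illness	mental illness	Mental health
mental disorder	mental illness	Mental health
depression	depression	Mental health
depressive disorder	depression	Mental health
antisocial personality disorder	antisocial personality disorder	Mental health
posttraumatic stress disorder	posttraumatic stress disorder	Mental health
post-traumatic stress disorder	posttraumatic stress disorder	Mental health
PTSD	posttraumatic stress disorder	Mental health
attention-deficit/hyperactivity disorder	attention-deficit/hyperactivity disorder	Mental health
attention deficit hyperactivity disorder	attention-deficit/hyperactivity disorder	Mental health
ADHD	attention-deficit/hyperactivity disorder	Mental health
psychopathology	psychopathology	Mental health
psychopathy	psychopathy	Mental health
depressive symptom	depressive symptom	Mental health
anxiety	anxiety	Mental health
schizophrenia	schizophrenia	Mental health
psychosis	psychosis	Mental health
substance use	substance use	Alcohol and other drug use
substance abuse	substance use	Alcohol and other drug use
drug use	substance use	Alcohol and other drug use
alcohol use	alcohol use	Alcohol and other drug use
alcohol	alcohol use	Alcohol and other drug use
alcohol abuse	alcohol use	Alcohol and other drug use
cannabis	cannabis	Alcohol and other drug use
marijuana	cannabis	Alcohol and other drug use
cocaine	cocaine	Alcohol and other drug use
cocaine abuse	cocaine abuse	Alcohol and other drug use
adolescent substance use	adolescent substance use	Alcohol and other drug use
intravenous drug	intravenous drug	Alcohol and other drug use
opioids	opioids	Alcohol and other drug use
opioid	opioids	Alcohol and other drug use
nicotine	nicotine	Alcohol and other drug use
nicotine addiction	nicotine addiction	Alcohol and other drug use
alcohol-related harm	alcohol-related harm	Alcohol and other drug use
heroin	heroin	Alcohol and other drug use
treatment	treatment	Health care service
screening program	screening program	Health care service
treatment completion	treatment completion	Health care service
school performance	school performance	Education (from health to vocational)
academic difficulties	academic difficulties	Education (from health to vocational)
maternal connectedness	maternal connectedness	Women's and maternal health
motherhood	motherhood	Women's and maternal health
stable home environment	stable home environment	Social determinants of health
childhood sexual abuse	childhood sexual abuse	Social determinants of health
school connectedness	school connectedness	Social determinants of health
bullying	bullying	Social determinants of health
nutritional improvements	nutritional improvements	Nutrition
food supplements	food supplements	Nutrition
learning disability	learning disability	Cognitive and intellectual disability
intellectual disability	intellectual disability	Cognitive and intellectual disability
sanctions	sanctions	Justice system
jail sanctions	sanctions	Justice system
law	law	Justice system
adjudication	adjudication	Justice system
mortality	mortality	Biomedical related
age	age	Biomedical related
sex	sex	Biomedical related
gender	gender	Biomedical related
injury	injury	Biomedical related
severe injury	severe injury	Biomedical related
spinal cord injury	spinal cord injury	Biomedical related
youth	youth	Biomedical related
5httplr	5httplr	Biomedical related
crime	crime	Offense related
recidivism	recidivism	Offense related
rearrests	rearrests	Offense related
offense	offense	Offense related
offence	offense	Offense related
homicide	homicide	Offense related
sexual homicide	sexual homicide	Offense related
arson	arson	Offense related
criminality	criminality	Offense related
delinquency	delinquency	Juveniles
adolescent delinquency	adolescent delinquency	Juveniles
offspring disinhibited behavior	offspring disinhibited behavior	Juveniles
violence	violence	Behavior
aggressive behaviour	aggressive behaviour	Behavior
aggressive behavior	aggressive behaviour	Behavior
acculturation	acculturation	Behavior
male-male sex	male-male sex	Behavior
church attendance	church attendance	
accountability	accountability	
job satisfaction	job satisfaction	
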