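indi_pt
Urinary tract infection
Pneumonia
Bronchitis
Sinusitis
Cystitis
Prostatitis
Pyelonephritis
Diverticulitis
Cellulitis
Gastroenteritis
Salmonellosis
Bronchitis chronic
Chronic obstructive pulmonary disease
Pneumonia bacterial
Sepsis
Otitis media
Conjunctivitis
Diarrhoea infectious
Traveller's diarrhoea
Anthrax
Plague
Typhoid fever
Gonorrhoea
Chlamydial infection
Tuberculosis
Helicobacter gastritis
Osteomyelitis
Septic shock
Abscess
Appendicitis
Cholecystitis
Peritonitis
Epididymitis
Pelvic inflammatory disease
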