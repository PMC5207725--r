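name,bddcs_class,percent_metabolised_human,major_cyps,cyp_note,trout_observed_metabolised
Atenolol,3,6.00,2D6,,FALSE
Carbamazepine,2,99.50,3A4,,FALSE
Diazepam,1,99.50,2C19;3A4,,FALSE
Diclofenac sodium salt,1,99.50,2C9;2C8;2C18;2C19;2B6,Believed principally CYP2C and likely 2C9; several minor enzymes (2C8 2C18 2C19 2B6) produce a wide range of metabolites,TRUE
Metoprolol succinate,1,99.00,2D6,,FALSE
Phenylbutazone,1,99.00,2D6;2C19;3A4,,TRUE
Propranolol HCl,1,99.75,1A2;2D6,,TRUE
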