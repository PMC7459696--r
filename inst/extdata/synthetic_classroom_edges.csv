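"source","target","wave"
"c02","c01","T0"
"c05","c01","T0"
"c09","c01","T0"
"c10","c01","T0"
"c12","c01","T0"
"c14","c01","T0"
"c06","c02","T0"
"c08","c02","T0"
"c12","c02","T0"
"c08","c03","T0"
"c10","c03","T0"
"c12","c03","T0"
"c14","c03","T0"
"c08","c04","T0"
"c10","c04","T0"
"c11","c04","T0"
"c12","c04","T0"
"c06","c05","T0"
"c09","c05","T0"
"c02","c06","T0"
"c04","c06","T0"
"c05","c06","T0"
"c07","c06","T0"
"c08","c06","T0"
"c11","c06","T0"
"c12","c06","T0"
"c02","c08","T0"
"c04","c08","T0"
"c06","c08","T0"
"c07","c08","T0"
"c11","c08","T0"
"c13","c08","T0"
"c02","c10","T0"
"c03","c10","T0"
"c06","c10","T0"
"c07","c10","T0"
"c12","c10","T0"
"c14","c10","T0"
"c09","c11","T0"
"c14","c11","T0"
"c01","c12","T0"
"c03","c12","T0"
"c05","c12","T0"
"c10","c12","T0"
"c13","c12","T0"
"c14","c12","T0"
"c10","c14","T0"
"c11","c14","T0"
"c04","c01","T1"
"c06","c01","T1"
"c11","c01","T1"
"c13","c01","T1"
"c11","c02","T1"
"c13","c02","T1"
"c01","c03","T1"
"c02","c03","T1"
"c09","c03","T1"
"c01","c04","T1"
"c02","c04","T1"
"c06","c04","T1"
"c13","c04","T1"
"c01","c05","T1"
"c02","c05","T1"
"c07","c05","T1"
"c08","c05","T1"
"c11","c05","T1"
"c10","c06","T1"
"c13","c06","T1"
"c06","c07","T1"
"c09","c07","T1"
"c11","c07","T1"
"c10","c08","T1"
"c02","c09","T1"
"c04","c09","T1"
"c06","c09","T1"
"c08","c09","T1"
"c11","c09","T1"
"c13","c09","T1"
"c05","c10","T1"
"c04","c11","T1"
"c06","c11","T1"
"c07","c11","T1"
"c08","c11","T1"
"c12","c11","T1"
"c03","c13","T1"
"c04","c13","T1"
"c06","c13","T1"
"c07","c13","T1"
"c08","c13","T1"
"c09","c13","T1"
"c01","c14","T1"
"c02","c14","T1"
"c04","c14","T1"
"c07","c14","T1"
"c08","c14","T1"
"c09","c14","T1"
"c02","c01","T1"
"c05","c01","T1"
"c09","c01","T1"
"c10","c01","T1"
"c12","c01","T1"
"c06","c02","T1"
"c08","c02","T1"
"c08","c03","T1"
"c10","c03","T1"
"c12","c03","T1"
"c14","c03","T1"
"c08","c04","T1"
"c10","c04","T1"
"c11","c04","T1"
"c12","c04","T1"
"c06","c05","T1"
"c09","c05","T1"
"c02","c06","T1"
"c05","c06","T1"
"c07","c06","T1"
"c08","c06","T1"
"c11","c06","T1"
"c12","c06","T1"
"c02","c08","T1"
"c04","c08","T1"
"c06","c08","T1"
"c07","c08","T1"
"c13","c08","T1"
"c02","c10","T1"
"c03","c10","T1"
"c07","c10","T1"
"c12","c10","T1"
"c14","c10","T1"
"c09","c11","T1"
"c14","c11","T1"
"c03","c12","T1"
"c05","c12","T1"
"c13","c12","T1"
"c14","c12","T1"
"c10","c14","T1"
"c11","c14","T1"
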