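vocabulary,source_code,concept_id
Gender,F,8532
Country,CO,4330422
Type,synthetic-record,900000001
SNOMED-CT,34801009,4400001
SNOMED-CT,19169002,4400002
SNOMED-CT,85116003,4400003
SNOMED-CT,48194001,4400004
SNOMED-CT,38341003,4400005
SNOMED-CT,37618003,4400006
SNOMED-CT,398254007,4400007
SNOMED-CT,198992004,4400008
SNOMED-CT,40801000119106,4400009
SNOMED-CT,22033007,4400010
SNOMED-CT,106004004,4400011
SNOMED-CT,36813001,4400012
SNOMED-CT,44223004,4400013
SNOMED-CT,415105001,4400014
SNOMED-CT,367494004,4400015
SNOMED-CT,47821001,4400016
SNOMED-CT,424525001,4410001
SNOMED-CT,169230002,4410002
SNOMED-CT,50849002,4410003
SNOMED-CT,183460006,4410004
SNOMED-CT,133906008,4410005
SNOMED-CT,386637004,4410006
SNOMED-CT,127786006,4420001
SNOMED-CT,86198006,4420002
SNOMED-CT,399014008,4420003
SNOMED-CT,48782003,4420004
SNOMED-CT,412726003,4420005
SNOMED-CT,21243004,4420006
CUPS,881431,4430001
CUPS,695101,4430002
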