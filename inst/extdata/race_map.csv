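source,target
WHITE,White
CAUCASIAN,White
BLACK,Black or African American
BLACK OR AFRICAN AMERICAN,Black or African American
AFRICAN AMERICAN,Black or African American
ASIAN,Asian
ORIENTAL,Asian
AMERICAN INDIAN OR ALASKA NATIVE,American Indian or Alaska Native
AMERICAN INDIAN,American Indian or Alaska Native
ALASKA NATIVE,American Indian or Alaska Native
NATIVE HAWAIIAN OR OTHER PACIFIC ISLANDER,Native Hawaiian or Other Pacific Islander
PACIFIC ISLANDER,Native Hawaiian or Other Pacific Islander
NATIVE HAWAIIAN,Native Hawaiian or Other Pacific Islander
MULTIPLE,Other/Multiple
MULTIRACIAL,Other/Multiple
MIXED,Other/Multiple
OTHER,Other/Multiple
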