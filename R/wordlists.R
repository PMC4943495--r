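# Small deterministic word lists for the synthetic trial generator. Shipping
# a fixed list (rather than an external corpus) keeps planted identifiers
# reproducible and download-free.

SYN_FIRST_NAMES <- c("Alice", "Benjamin", "Clara", "Daniel", "Elena",
                     "Felix", "Grace", "Henrik", "Ines", "Jonas", "Katya",
                     "Liam", "Maria", "Noah", "Olivia", "Pavel", "Quinn",
                     "Rosa", "Samuel", "Tara")

SYN_LAST_NAMES <- c("Andersson", "Baker", "Costa", "Dubois", "Evans",
                    "Fischer", "Garcia", "Hansen", "Ivanov", "Jensen",
                    "Kowalski", "Lindqvist", "Moreau", "Novak", "Okafor",
                    "Petrov", "Quintero", "Rossi", "Schmidt", "Tanaka")

SYN_COUNTRIES <- c("USA", "DEU", "FRA", "GBR", "ESP", "ITA", "POL", "JPN")

# collected race spellings deliberately mix CDISC terms, legacy shorthand
# and one unmappable value to exercise the review route
SYN_RACES <- c("WHITE", "BLACK OR AFRICAN AMERICAN", "ASIAN", "BLACK",
               "AMERICAN INDIAN OR ALASKA NATIVE",
               "NATIVE HAWAIIAN OR OTHER PACIFIC ISLANDER",
               "CAUCASIAN", "MULTIPLE", "OTHER")

SYN_ETHNICITIES <- c("HISPANIC OR LATINO", "NOT HISPANIC OR LATINO",
                     "NOT REPORTED")

# verbatim phrase stems paired with MedDRA-style preferred terms; stems are
# word-only so the scanner's digit patterns never fire on the base text
SYN_AE_TERMS <- data.frame(
  verbatim = c("terrible headache all day", "mild nausea after dosing",
               "dizzy spells on standing", "itchy rash on both arms",
               "pain in lower back", "dry cough at night",
               "felt very tired", "stomach upset and cramping",
               "sore throat and sniffles", "trouble sleeping"),
  decod = c("Headache", "Nausea", "Dizziness", "Rash", "Back pain",
            "Cough", "Fatigue", "Abdominal discomfort",
            "Nasopharyngitis", "Insomnia"),
  stringsAsFactors = FALSE)
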