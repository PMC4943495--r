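# The eighteen HIPAA Safe Harbor direct identifier classes, as exposed by
# trialdeid::builtin_registry(). `detection` names the value-pattern family
# (if any) used by the cell scanner; classes without a computable pattern are
# handled at the variable level by role declaration.
identifiers:
  - {code: A, label: "Name", detection: name-like}
  - {code: B, label: "Geographic subdivisions smaller than a state", detection: zip}
  - {code: C, label: "All elements of dates (except year) directly related to an individual; ages over 89", detection: date-like}
  - {code: D, label: "Telephone numbers", detection: phone}
  - {code: E, label: "Fax numbers", detection: phone}
  - {code: F, label: "Email addresses", detection: email}
  - {code: G, label: "Social security numbers", detection: ssn-like}
  - {code: H, label: "Medical record numbers", detection: account-like}
  - {code: I, label: "Health plan beneficiary numbers", detection: account-like}
  - {code: J, label: "Account numbers", detection: account-like}
  - {code: K, label: "Certificate/licence numbers", detection: none}
  - {code: L, label: "Vehicle identifiers and serial numbers, including license plate numbers", detection: none}
  - {code: M, label: "Device identifiers and serial numbers", detection: none}
  - {code: N, label: "Web Universal Resource Locators (URLs)", detection: url}
  - {code: O, label: "Internet Protocol (IP) addresses", detection: ip}
  - {code: P, label: "Biometric identifiers, including finger and voice prints", detection: none}
  - {code: Q, label: "Full-face photographs and any comparable images", detection: none}
  - {code: R, label: "Any other unique identifying number, characteristic, or code", detection: none}
attestation: >
  The covered entity does not have actual knowledge that the remaining
  information could be used alone or in combination with other information
  to identify an individual who is a subject of the information.
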