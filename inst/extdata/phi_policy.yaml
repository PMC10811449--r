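# Default PHI masking policy: the standard DICOM attribute-confidentiality
# set carried by this package's fixtures. Actions: blank, remove_value, or
# fixed_literal:<text>. Tag *names* are always preserved; only values are
# masked. PatientID is not listed here because the pipeline replaces it with
# a keyed token instead of blanking it. This default is a starting point and
# must be reviewed/extended for any site-specific certification.
PatientName: blank
PatientBirthDate: blank
OtherPatientIDs: blank
PatientAddress: blank
PatientTelephoneNumbers: blank
InstitutionName: "fixed_literal:MASKED"
InstitutionAddress: blank
ReferringPhysicianName: blank
OperatorsName: blank
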