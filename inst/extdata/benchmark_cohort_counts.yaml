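# Reference cohort counts from a published two-practice ophthalmic imaging
# archive linked to an EHR registry; used by the worked example and the
# acceptance script as inputs to the rate computations. Counts are integers
# as printed; all rates are recomputed by the package.
totals:
  patients: 54896
  linked_patients: 46196
  images: 2287839
  linked_images: 1937864
  visits: 250954
  linked_visits: 221079
exclusions:
  NAME_NUMERIC_OR_SPECIAL: {patients: 2365, images: 207628}
  ABNORMAL_DOB: {patients: 118, images: 3447}
  TEST_NAME: {patients: 17, images: 456}
year_strata:
  - {label: "2020-2021", total_images: 468767, linked_images: 445163}
  - {label: "2019-2020", total_images: 740436, linked_images: 676465}
  - {label: "2018-2019", total_images: 308612, linked_images: 274900}
  - {label: "2017-2018", total_images: 281791, linked_images: 223138}
  - {label: "2016-2017", total_images: 209847, linked_images: 135118}
  - {label: "2015-2016", total_images: 158928, linked_images: 103607}
  - {label: "2014-2015", total_images: 119458, linked_images: 79473}
type_strata:
  - {label: "OCT", total_patients: 35741, linked_patients: 30087}
  - {label: "FAF", total_patients: 24433, linked_patients: 21745}
  - {label: "IR", total_patients: 47168, linked_patients: 40121}
  - {label: "COLOR", total_patients: 24717, linked_patients: 22218}
  - {label: "FA", total_patients: 22130, linked_patients: 19447}
  - {label: "ICGA", total_patients: 1828, linked_patients: 1666}
  - {label: "BR", total_patients: 3596, linked_patients: 2750}
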