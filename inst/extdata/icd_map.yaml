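# Diagnosis cohorts and their ICD-10 code sets. These defaults are
# package-supplied approximations of common coding practice for each
# ophthalmic diagnosis and should be replaced by a site's certified code
# list before use on real data. A patient may belong to several cohorts.
diabetic_retinopathy_with_macular_edema:
  - E11.311
  - E11.321
  - E11.331
  - E11.341
  - E11.351
diabetic_retinopathy_without_macular_edema:
  - E11.319
  - E11.329
  - E11.339
  - E11.349
  - E11.359
exudative_amd:
  - H35.32
  - H35.3210
  - H35.3220
non_exudative_amd:
  - H35.31
  - H35.3110
  - H35.3120
geographic_atrophy:
  - H35.3113
  - H35.3123
  - H35.3133
glaucoma:
  - H40.10
  - H40.11
  - H40.9
retinal_vascular_occlusions:
  - H34.81
  - H34.83
  - H34.9
choroidal_disorders:
  - H31.9
  - H31.1
  - H31.2
hereditary_retinal_dystrophy:
  - H35.50
  - H35.51
  - H35.52
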