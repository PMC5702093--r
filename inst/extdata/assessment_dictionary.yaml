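# Machine-readable data dictionary for assessment CSV files.
# Each entry: type (id|date|code|numeric|factor), allowed codes or range,
# and whether the column is mandatory. Validation of parse_assessments()
# is driven entirely by this file.
columns:
  person_id:        {type: id,      required: true}
  assessment_date:  {type: date,    required: true}
  bathing:          {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  personal_hygiene: {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  dressing_upper:   {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  dressing_lower:   {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  walking_indoors:  {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  walking_outdoors: {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  locomotion:       {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  toilet_use:       {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  eating:           {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  bed_mobility:     {type: code, codes: [0,1,2,3,4,5,6,8], required: true}
  decision_making:  {type: code, codes: [0,1,2,3,4], required: true}
  short_term_memory_ok: {type: code, codes: [0,1], required: true}
  making_self_understood: {type: code, codes: [0,1,2,3,4], required: true}
  meal_preparation:   {type: code, codes: [0,1,2], required: true}
  ordinary_housework: {type: code, codes: [0,1,2], required: true}
  phone_use:          {type: code, codes: [0,1,2], required: true}
  bladder_incontinence: {type: code, codes: [0,1,2,3,4,5], required: true}
  bowel_incontinence:   {type: code, codes: [0,1,2,3,4,5], required: true}
  unstable_conditions:  {type: code, codes: [0,1], required: true}
  caregiver_distress:   {type: code, codes: [0,1], required: true}
  estimated_aide_minutes:       {type: numeric, min: 0, required: true}
  estimated_homemaking_minutes: {type: numeric, min: 0, required: true}
  age:          {type: numeric, min: 18, max: 115, required: true}
  sex:          {type: factor, levels: [F, M], required: true}
  living_alone: {type: code, codes: [0,1], required: true}
  setting:      {type: factor, levels: [community, retirement_home, supportive_housing, assisted_living], required: true}
  on_waitlist_or_hold: {type: code, codes: [0,1], required: true}
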