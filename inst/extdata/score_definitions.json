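{
  "schema_version": "1.0.0",
  "notes": "Rubrics for six massive-transfusion prediction scores. Each criterion is a declarative predicate over patient-record fields. Criteria sharing a 'group' are mutually exclusive bands: they are listed most-severe-first and only the first satisfied band awards its points. Point weights for TASH, ABC, Larson, PWH and ETS are transcribed from the primary publications named in 'source'; provenance per criterion is in 'note' where non-obvious.",
  "scores": {
    "mticcs": {
      "label": "mTICCS",
      "source": "Tonglet et al. 2014 (original TICCS rubric); modified variant: constitutive resuscitation-room criterion and side-pooled extremity criteria",
      "min_score": 2,
      "max_score": 16,
      "criteria": [
        {"name": "general_severity", "op": "const", "points": 2,
         "note": "admitted into resuscitation room with trauma team activation; constitutively awarded for severely injured (ISS >= 16) cohorts"},
        {"name": "sbp_ever_below_90", "op": "flag", "field": "sbp_ever_below_90", "points": 5,
         "note": "systolic blood pressure fell below 90 mmHg at least once"},
        {"name": "severe_head_neck", "op": "ais_ge", "regions": ["head", "neck"], "value": 3, "points": 1},
        {"name": "severe_upper_extremity", "op": "ais_ge", "regions": ["upper_extremity"], "value": 3, "points": 1},
        {"name": "severe_lower_extremity", "op": "ais_ge", "regions": ["lower_extremity"], "value": 3, "points": 1},
        {"name": "severe_torso", "op": "ais_ge", "regions": ["thorax"], "value": 3, "points": 2},
        {"name": "severe_abdomen", "op": "ais_ge", "regions": ["abdomen"], "value": 3, "points": 2},
        {"name": "severe_pelvis", "op": "ais_ge", "regions": ["pelvis"], "value": 3, "points": 2}
      ]
    },
    "tash": {
      "label": "TASH",
      "source": "Yuecel et al. 2006, J Trauma 60(6):1228-1237 (Trauma Associated Severe Hemorrhage score)",
      "min_score": 0,
      "max_score": 28,
      "logistic_transform": {"intercept": -4.9, "slope": 0.3,
        "note": "p(MT) = 1 / (1 + exp(4.9 - 0.3 * score)) as published; gives 0.475 at score 16"},
      "criteria": [
        {"name": "sbp_lt_100", "op": "lt", "field": "sbp_initial", "value": 100, "points": 4, "group": "sbp"},
        {"name": "sbp_lt_120", "op": "lt", "field": "sbp_initial", "value": 120, "points": 1, "group": "sbp"},
        {"name": "hb_lt_7",  "op": "lt", "field": "hb", "value": 7,  "points": 8, "group": "hb"},
        {"name": "hb_lt_9",  "op": "lt", "field": "hb", "value": 9,  "points": 6, "group": "hb"},
        {"name": "hb_lt_10", "op": "lt", "field": "hb", "value": 10, "points": 4, "group": "hb"},
        {"name": "hb_lt_11", "op": "lt", "field": "hb", "value": 11, "points": 3, "group": "hb"},
        {"name": "hb_lt_12", "op": "lt", "field": "hb", "value": 12, "points": 2, "group": "hb"},
        {"name": "fast_positive", "op": "flag", "field": "fast_positive", "points": 3,
         "note": "intraabdominal free fluid on FAST"},
        {"name": "pelvis_unstable", "op": "flag", "field": "pelvic_ring_unstable", "points": 6, "group": "fracture",
         "note": "clinically unstable pelvic fracture; fracture group is mutually exclusive so the maximum total is 28"},
        {"name": "femur_open_or_dislocated", "op": "flag", "field": "femur_fracture_open_or_dislocated", "points": 3, "group": "fracture"},
        {"name": "hr_gt_120", "op": "gt", "field": "hr", "value": 120, "points": 2},
        {"name": "be_lt_m10", "op": "lt", "field": "base_excess", "value": -10, "points": 4, "group": "be"},
        {"name": "be_lt_m6",  "op": "lt", "field": "base_excess", "value": -6,  "points": 3, "group": "be"},
        {"name": "be_lt_m2",  "op": "lt", "field": "base_excess", "value": -2,  "points": 1, "group": "be"},
        {"name": "male_sex", "op": "eq", "field": "sex", "value": "male", "points": 1}
      ]
    },
    "abc": {
      "label": "ABC",
      "source": "Nunez et al. 2009, J Trauma 66(2):346-352 (Assessment of Blood Consumption score)",
      "min_score": 0,
      "max_score": 4,
      "criteria": [
        {"name": "penetrating_mechanism", "op": "eq", "field": "mechanism", "value": "penetrating", "points": 1},
        {"name": "sbp_le_90", "op": "le", "field": "sbp_initial", "value": 90, "points": 1},
        {"name": "hr_ge_120", "op": "ge", "field": "hr", "value": 120, "points": 1},
        {"name": "fast_positive", "op": "flag", "field": "fast_positive", "points": 1}
      ]
    },
    "larson": {
      "label": "Larson",
      "source": "Larson et al. 2010, J Trauma 69 Suppl 1:S33-S39 (Joint Theater Trauma Registry score)",
      "min_score": 0,
      "max_score": 4,
      "criteria": [
        {"name": "hr_ge_105", "op": "ge", "field": "hr", "value": 105, "points": 1},
        {"name": "sbp_le_110", "op": "le", "field": "sbp_initial", "value": 110, "points": 1},
        {"name": "hb_le_11", "op": "le", "field": "hb", "value": 11, "points": 1},
        {"name": "base_deficit_ge_6", "op": "le", "field": "base_excess", "value": -6, "points": 1,
         "note": "published as base deficit >= 6 mEq/L, i.e. base excess <= -6"}
      ]
    },
    "pwh": {
      "label": "PWH",
      "source": "Rainer et al. 2011, Resuscitation 82(6):724-729 (Prince of Wales Hospital score)",
      "min_score": 0,
      "max_score": 18,
      "criteria": [
        {"name": "hr_ge_120", "op": "ge", "field": "hr", "value": 120, "points": 1},
        {"name": "sbp_le_90", "op": "le", "field": "sbp_initial", "value": 90, "points": 2},
        {"name": "gcs_le_8", "op": "le", "field": "gcs", "value": 8, "points": 1},
        {"name": "pelvic_fracture_displaced", "op": "flag", "field": "pelvic_fracture_displaced", "points": 1},
        {"name": "ct_or_fast_fluid", "op": "flag_any", "fields": ["ct_fluid_positive", "fast_positive"], "points": 2,
         "note": "CT scan or FAST positive for free fluid"},
        {"name": "base_deficit_gt_5", "op": "lt", "field": "base_excess", "value": -5, "points": 1,
         "note": "published as base deficit > 5 mmol/L, i.e. base excess < -5"},
        {"name": "hb_le_7",  "op": "le", "field": "hb", "value": 7,  "points": 10, "group": "hb"},
        {"name": "hb_le_10", "op": "le", "field": "hb", "value": 10, "points": 1,  "group": "hb",
         "note": "published band 7.1-10.0 g/dL; band exclusivity handled by the group"}
      ]
    },
    "ets": {
      "label": "ETS",
      "source": "Kuhne et al. 2008, World J Surg 32(6):1183-1188 (Emergency Transfusion Score)",
      "min_score": 0,
      "max_score": 9.5,
      "criteria": [
        {"name": "sbp_lt_90",  "op": "lt", "field": "sbp_initial", "value": 90,  "points": 2.5, "group": "sbp"},
        {"name": "sbp_90_120", "op": "le", "field": "sbp_initial", "value": 120, "points": 1.5, "group": "sbp",
         "note": "published band 90-120 mmHg; lower bound enforced by group order"},
        {"name": "free_fluid_ultrasound", "op": "flag", "field": "fast_positive", "points": 2},
        {"name": "pelvic_ring_unstable", "op": "flag", "field": "pelvic_ring_unstable", "points": 1.5,
         "note": "clinically unstable pelvic ring fracture"},
        {"name": "age_gt_60", "op": "gt", "field": "age", "value": 60, "points": 1.5, "group": "age"},
        {"name": "age_20_60", "op": "ge", "field": "age", "value": 20, "points": 0.5, "group": "age"},
        {"name": "admitted_from_scene", "op": "flag", "field": "admitted_from_scene", "points": 1},
        {"name": "traffic_accident", "op": "in", "field": "mechanism_subtype",
         "values": ["car", "motorbike", "bicycle", "pedestrian"], "points": 1, "group": "mechanism_event"},
        {"name": "fall_gt_3m", "op": "eq", "field": "mechanism_subtype", "value": "fall_gt3m", "points": 1, "group": "mechanism_event",
         "note": "traffic accident and fall > 3 m treated as mutually exclusive event types, giving the published maximum of 9.5"}
      ]
    }
  }
}
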