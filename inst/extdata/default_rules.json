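{
  "version": "seed-1.0",
  "rules": [
    {
      "id": "risk_factor_for",
      "anchor": "\\b(?:is|was|are|were|remains?|remained)\\s+(?:an?\\s+)?(?:\\w+\\s+){0,2}?(?:risk|protective)\\s+factors?\\s+(?:for|of|against)\\b",
      "slots": [
        {
          "side": "left",
          "max_token_gap": 6,
          "allow_coordination": true
        },
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "risk_factor_head",
      "anchor": "\\b(?:risk|protective)\\s+factors?\\s+(?:for|of)\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "risk_factor_trailing",
      "anchor": "\\b(?:is|was|are|were)\\s+(?:among\\s+|the\\s+|an?\\s+|significant\\s+|independent\\s+|major\\s+|strong\\s+|important\\s+)*(?:risk|protective)\\s+factors?\\b",
      "slots": [
        {
          "side": "left",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "predictors_of",
      "anchor": "\\bpredict(?:ors?|ion)\\s+of\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "predictive_of",
      "anchor": "\\b(?:is|was|are|were)\\s+(?:\\w+\\s+){0,2}?predict(?:ive|ors?)\\s+of\\b",
      "slots": [
        {
          "side": "left",
          "max_token_gap": 6,
          "allow_coordination": true
        },
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "predicted",
      "anchor": "\\bpredict(?:ed|s)\\b",
      "slots": [
        {
          "side": "left",
          "max_token_gap": 4,
          "allow_coordination": true
        },
        {
          "side": "right",
          "max_token_gap": 4,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "associated_with",
      "anchor": "\\b(?:is|was|are|were|be|been)\\s+(?:\\w+\\s+){0,2}?associated\\s+with\\b",
      "slots": [
        {
          "side": "left",
          "max_token_gap": 6,
          "allow_coordination": true
        },
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "association_between",
      "anchor": "\\bassociations?\\s+between\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 8,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "related_to",
      "anchor": "\\b(?:is|was|are|were|be|been)\\s+(?:\\w+\\s+){0,2}?(?:related|linked)\\s+to\\b",
      "slots": [
        {
          "side": "left",
          "max_token_gap": 6,
          "allow_coordination": true
        },
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "correlated_with",
      "anchor": "\\bcorrelat(?:ed|es|e)\\s+with\\b",
      "slots": [
        {
          "side": "left",
          "max_token_gap": 6,
          "allow_coordination": true
        },
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "prevalence_of",
      "anchor": "\\b(?:prevalence|incidence|rates?|burden)\\s+of\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 4,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "deaths_from",
      "anchor": "\\b(?:deaths?|mortality)\\s+(?:from|due\\s+to)\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 4,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "effect_on",
      "anchor": "\\b(?:effects?|impacts?)\\s+of\\b[^.;:]{1,60}?\\s+on\\b",
      "slots": [
        {
          "side": "within",
          "max_token_gap": 0,
          "allow_coordination": true
        },
        {
          "side": "right",
          "max_token_gap": 6,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "history_of",
      "anchor": "\\b(?:history|diagnosis|diagnoses)\\s+of\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 4,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "suffering_from",
      "anchor": "\\bsuffer(?:ed|ing|s)?\\s+from\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 4,
          "allow_coordination": true
        }
      ]
    },
    {
      "id": "screened_for",
      "anchor": "\\b(?:screened|tested)\\s+(?:positive\\s+)?for\\b",
      "slots": [
        {
          "side": "right",
          "max_token_gap": 4,
          "allow_coordination": true
        }
      ]
    }
  ]
}
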