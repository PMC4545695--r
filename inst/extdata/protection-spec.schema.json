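{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "netreduce protection specification",
  "description": "What a network reduction must preserve: protected metabolites and reactions, protected phenotypes (linear flux scenarios), and floors on degrees of freedom and reaction count. Usually written as YAML with this structure.",
  "type": "object",
  "properties": {
    "protected_metabolites": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Metabolite IDs that must keep at least one feasible reaction in the reduced network."
    },
    "protected_reactions": {
      "type": "array",
      "items": { "type": "string" },
      "description": "Reaction IDs that are never deleted."
    },
    "enforce_protected_feasibility": {
      "type": "boolean",
      "default": false,
      "description": "Require every protected reaction to be able to carry nonzero flux in at least one scenario."
    },
    "dof_min": {
      "type": "integer",
      "minimum": 0,
      "default": 0,
      "description": "Minimum degrees of freedom (n - rank of the stoichiometric matrix) of the reduced network; 0 disables the constraint."
    },
    "n_min": {
      "type": "integer",
      "minimum": 1,
      "default": 1,
      "description": "Minimum number of reactions in the reduced network."
    },
    "scenarios": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "name": { "type": "string" },
          "constraints": {
            "type": "array",
            "items": {
              "type": "string",
              "description": "Linear constraint over reaction IDs with literal coefficients, e.g. 'R_glc_up <= 10' or '-mu <= -0.999 * FBA_MAX(mu)'. Relations <=, >= and =; FBA_MAX(rxn) is resolved to the maximum of rxn's flux on the full model under the scenario's other constraints."
            }
          },
          "bound_overrides": {
            "type": "object",
            "additionalProperties": {
              "type": "array",
              "items": { "type": "number" },
              "minItems": 2,
              "maxItems": 2,
              "description": "[lb, ub] applied to the named reaction within this scenario only."
            }
          }
        },
        "required": ["name"]
      }
    }
  },
  "additionalProperties": false
}
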