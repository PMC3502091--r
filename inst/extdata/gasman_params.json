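{
  "description": "Packaged model parameters: agent solubilities (blood/gas and tissue/gas partition coefficients), 1-MAC partial pressures, overpressure vaporizer settings, and default patient/circuit constants.",
  "agents": [
    {
      "name": "desflurane",
      "mac": 6.0,
      "lambda_blood": 0.42,
      "lambda_vrg": 0.54,
      "lambda_mus": 0.97,
      "lambda_fat": 13,
      "overpressure_fd": 18
    },
    {
      "name": "sevoflurane",
      "mac": 2.0,
      "lambda_blood": 0.65,
      "lambda_vrg": 1.1,
      "lambda_mus": 2.4,
      "lambda_fat": 34,
      "overpressure_fd": 5
    },
    {
      "name": "isoflurane",
      "mac": 1.2,
      "lambda_blood": 1.3,
      "lambda_vrg": 2.1,
      "lambda_mus": 4.5,
      "lambda_fat": 70,
      "overpressure_fd": 3
    }
  ],
  "body": {
    "weight": 70,
    "v_circuit": 8,
    "frc": 2.5,
    "q_total": 5,
    "v_vrg": 6,
    "v_mus": 33,
    "v_fat": 14.5,
    "f_vrg": 0.758,
    "f_mus": 0.18,
    "f_fat": 0.06
  }
}
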