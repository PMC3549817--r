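{"version":"0.1.0","features":["F1","F2","F4"],"weights":{"F1":"19.993888481071508","F2":"-21.493356266091588","F4":"-4.1378879339859509e-05"},"bias":"-14.995584572956314","C":"32","cv_accuracy":"0.9925729442970822","norm_min":{"F1":"2","F2":"2","F4":"-24.213014213309904"},"norm_max":{"F1":"10","F2":"45","F4":"-3.6926474113640939"},"folds":5,"seed":20260901}
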