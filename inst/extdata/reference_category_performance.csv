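feed_category,top_models,lower_models,bic_top,bic_lower,bic_all,difference,rpi
Compound,Dagum;Burr XII;Inverse paralogistic;Log-logistic;Paralogistic,Cauchy;Gumbel,29.6,58.0,40.1,28.4,70.8
Corn,Log-logistic;Dagum;Burr XII;Paralogistic,Cauchy;Generalized logistic,37.1,58.9,48.2,21.8,45.2
Processed protein,Dagum;Burr XII;Inverse paralogistic;Log-logistic;Paralogistic,Cauchy;Gumbel,22.6,55.0,34.4,32.4,94.2
Legumes,Dagum;Burr XII;Inverse paralogistic;Log-logistic;Paralogistic,Gumbel,29.6,61.0,42.9,31.4,73.2
Soft cereal,Inverse paralogistic;Log-logistic;Burr XII,Gumbel,44.7,62.6,52.0,17.9,34.4
Others,Dagum;Burr XII;Inverse paralogistic;Log-logistic;Paralogistic,Cauchy;Gumbel,35.5,58.0,43.6,22.5,51.6
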