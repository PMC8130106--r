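question,response,system,count
satisfaction,very_satisfied,internalized,15
satisfaction,satisfied,internalized,6
satisfaction,dissatisfied,internalized,0
satisfaction,very_dissatisfied,internalized,0
satisfaction,very_satisfied,external,2
satisfaction,satisfied,external,12
satisfaction,dissatisfied,external,2
satisfaction,very_dissatisfied,external,1
quality,very_good,internalized,15
quality,good,internalized,6
quality,bad,internalized,0
quality,very_bad,internalized,0
quality,very_good,external,2
quality,good,external,13
quality,bad,external,0
quality,very_bad,external,2
preference,external_company,comparison,0
preference,internalized_system,comparison,12
preference,both_equally,comparison,5
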