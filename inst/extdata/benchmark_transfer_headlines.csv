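label,strategy,task,dat,level,precision,recall,f1_reported
svm_best_transfer,SVM,Exp.3->Exp.2,6,NA,1.00,0.81,0.90
tca_best_task,TCA_SVM,Exp.3->Exp.2,6,NA,0.91,1.00,0.95
update_tca_6dat,Update_TCA_SVM,Exp.3->Exp.1,6,50,0.75,1.00,0.86
update_tca_8dat,Update_TCA_SVM,Exp.3->Exp.1,8,20,0.94,1.00,0.97
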