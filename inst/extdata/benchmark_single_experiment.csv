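experiment,dat,set,accuracy,precision,recall,f1,fpr
Exp.1,2-8,train,0.73,0.73,0.84,0.78,0.41
Exp.1,2-8,test,0.79,0.82,0.69,0.75,0.13
Exp.1,2,train,0.86,0.91,0.77,0.83,0.06
Exp.1,2,test,0.71,0.75,0.75,0.75,0.33
Exp.1,4,train,0.72,0.71,0.83,0.77,0.43
Exp.1,4,test,0.57,0.50,0.33,0.40,0.25
Exp.1,6,train,0.80,0.82,0.82,0.82,0.23
Exp.1,6,test,0.86,1,0.75,0.86,0
Exp.1,8,train,0.96,0.94,1,0.97,0.11
Exp.1,8,test,1,1,1,1,0
Exp.2,2-8,train,0.81,0.80,0.93,0.86,0.39
Exp.2,2-8,test,0.85,0.76,1,0.87,0.29
Exp.2,2,train,0.75,0.79,0.79,0.79,0.31
Exp.2,2,test,0.14,0,0,NaN,0.80
Exp.2,4,train,0.88,0.85,0.94,0.89,0.21
Exp.2,4,test,0.57,0.50,0.67,0.57,0.50
Exp.2,6,train,0.97,0.95,1,0.97,0.08
Exp.2,6,test,1,1,1,1,0
Exp.2,8,train,1,1,1,1,0
Exp.2,8,test,0.75,0.67,1,0.80,0.50
Exp.3,2-8,train,0.70,0.69,0.94,0.79,0.71
Exp.3,2-8,test,0.84,0.70,0.88,0.78,0.18
Exp.3,2,train,0.69,0.68,0.81,0.74,0.44
Exp.3,2,test,0.33,0.20,0.33,0.25,0.67
Exp.3,4,train,0.95,1,0.90,0.95,0
Exp.3,4,test,1,1,1,1,0
Exp.3,6,train,1,1,1,1,0
Exp.3,6,test,1,1,1,1,0
Exp.3,8,train,0.96,0.96,1,0.98,0.17
Exp.3,8,test,0.71,0.50,1,0.67,0.40
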